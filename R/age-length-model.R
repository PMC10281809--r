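# Cohort definition, the cohort-aware cubic age-length mixed model with a
# length/cohort dispersion component, and age prediction for non-aged fish.

#' Define recruitment cohorts from hatch dates
#'
#' A deterministic surrogate for visual cohort identification: hatch dates
#' are sorted and split wherever consecutive dates are more than `gap_days`
#' apart. Each cohort window spans the min-max hatch date of its members.
#'
#' @param hatch_dates `Date` vector (>= 1 date; >= 2 for a meaningful split).
#' @param gap_days gap threshold in days (default 30).
#' @return data.frame of class `cohort_windows` with columns `cohort_id`,
#'   `start_date`, `end_date`, `midpoint`, `n`.
#' @export
define_cohorts <- function(hatch_dates, gap_days = 30) {
  hatch_dates <- sort(as_date(hatch_dates[!is.na(hatch_dates)]))
  stopifnot(length(hatch_dates) >= 1, gap_days > 0)
  gaps <- diff(as.numeric(hatch_dates))
  grp <- cumsum(c(0, gaps > gap_days)) + 1L
  out <- do.call(rbind, lapply(split(hatch_dates, grp), function(d) {
    data.frame(start_date = min(d), end_date = max(d),
               midpoint = as.Date(round(mean(as.numeric(d))),
                                  origin = "1970-01-01"),
               n = length(d))
  }))
  out <- out[order(out$start_date), ]
  out$cohort_id <- sprintf("C%02d", seq_len(nrow(out)))
  rownames(out) <- NULL
  structure(out[, c("cohort_id", "start_date", "end_date", "midpoint", "n")],
            class = c("cohort_windows", "data.frame"))
}

# label aged fish with the cohort window containing their hatch date
cohort_of_hatch <- function(hatch_dates, cohorts) {
  vapply(as.numeric(as_date(hatch_dates)), function(h) {
    hit <- which(h >= as.numeric(cohorts$start_date) &
                   h <= as.numeric(cohorts$end_date))
    if (length(hit) >= 1) cohorts$cohort_id[hit[1]] else NA_character_
  }, character(1))
}

# Raw-scale cubic coefficients from a fitted mean function: evaluate the
# (exactly cubic) mean at four lengths and solve the Vandermonde system.
raw_cubic_coefficients <- function(mean_fun, length_range) {
  L <- seq(length_range[1], length_range[2], length.out = 4)
  V <- outer(L, 0:3, `^`)
  as.numeric(solve(V, mean_fun(L)))
}

#' Fit the cohort-aware cubic age-length model
#'
#' Post-settlement age (days) is modelled against a cubic polynomial in
#' total length with a Gaussian error structure, a random intercept per
#' recruitment cohort, and a log-linear dispersion model in total length and
#' cohort to absorb the decreasing ageing precision of longer fish. Fitting
#' uses an orthogonal polynomial basis internally; coefficients are reported
#' on the raw length scale.
#'
#' If the mixed fit fails to converge, the cohort variance is singular, or
#' the data are a near-exact interpolation (residual sd ~ 0, where the
#' dispersion MLE degenerates), the fitter falls back to a
#' fixed-cohort-intercept least-squares cubic and records that in the fit.
#'
#' @param fish aged fish records: `post_settlement_age_days`,
#'   `total_length_mm`, `hatch_date` present.
#' @param cohorts a [define_cohorts()] table.
#' @param mean_pld_days mean PLD carried along for cohort assignment of
#'   non-aged fish (default 28).
#' @return object of class `age_length_fit`.
#' @export
fit_age_length <- function(fish, cohorts, mean_pld_days = 28) {
  stopifnot(inherits(cohorts, "cohort_windows"))
  fish$cohort_id <- cohort_of_hatch(fish$hatch_date, cohorts)
  dat <- fish[!is.na(fish$post_settlement_age_days) &
                !is.na(fish$cohort_id), ]
  tab <- table(dat$cohort_id)
  if (length(tab) < 2 || any(tab < 5)) {
    stop("need >= 2 cohorts each with >= 5 aged fish (got ",
         paste(sprintf("%s:%d", names(tab), tab), collapse = ", "), ")")
  }
  dat$cohort_id <- factor(dat$cohort_id, levels = cohorts$cohort_id)
  dat$cohort_id <- droplevels(dat$cohort_id)
  length_range <- range(dat$total_length_mm)

  # near-interpolation guard: a pilot least-squares cubic with fixed cohort
  # intercepts; also the fallback fit
  pilot <- stats::lm(post_settlement_age_days ~
                       poly(total_length_mm, 3) + cohort_id, data = dat)
  pilot_sd <- suppressWarnings(summary(pilot)$sigma)
  fallback_reason <- NULL
  fit <- NULL
  if (pilot_sd < 1e-6) {
    fallback_reason <- "near-exact interpolation (residual sd ~ 0)"
  } else {
    fit <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(
        post_settlement_age_days ~ poly(total_length_mm, 3) + (1 | cohort_id),
        dispformula = ~ total_length_mm + cohort_id,
        family = stats::gaussian(), data = dat,
        control = glmmTMB::glmmTMBControl(
          optCtrl = list(iter.max = 1000, eval.max = 1000)))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      fallback_reason <- paste("glmmTMB error:", conditionMessage(fit))
      fit <- NULL
    } else if (!isTRUE(fit$sdr$pdHess)) {
      fallback_reason <- "non-positive-definite Hessian (non-convergence)"
      fit <- NULL
    } else {
      csd <- sqrt(glmmTMB::VarCorr(fit)$cond$cohort_id[1, 1])
      if (!is.finite(csd) || csd < 1e-8) {
        fallback_reason <- "singular cohort variance"
        fit <- NULL
      }
    }
  }

  if (is.null(fit)) {
    message("fit_age_length: falling back to fixed-cohort-intercept ",
            "least-squares cubic (", fallback_reason, ")")
    cf <- stats::coef(pilot)
    levs <- levels(dat$cohort_id)
    eff <- c(0, cf[paste0("cohort_id", levs[-1])])
    eff[is.na(eff)] <- 0
    eff <- eff - mean(eff)                      # centre so effects sum to 0
    names(eff) <- levs
    base <- function(L) {
      stats::predict(pilot, newdata = data.frame(
        total_length_mm = L, cohort_id = factor(levs[1], levels = levs))) -
        eff[levs[1]]
    }
    raw <- raw_cubic_coefficients(base, length_range)
    sd_fun <- function(L, cohort) rep(max(pilot_sd, 1e-12), length(L))
    cohort_sd <- stats::sd(eff)
    engine <- "lm-fallback"
    model <- pilot
  } else {
    re <- glmmTMB::ranef(fit)$cond$cohort_id
    eff <- stats::setNames(re[, 1], rownames(re))
    eff <- eff[levels(dat$cohort_id)]
    eff[is.na(eff)] <- 0
    marg <- function(L) {
      stats::predict(fit, newdata = data.frame(
        total_length_mm = L,
        cohort_id = factor(NA, levels = levels(dat$cohort_id))),
        re.form = NA, allow.new.levels = TRUE)
    }
    raw <- raw_cubic_coefficients(marg, length_range)
    disp_beta <- glmmTMB::fixef(fit)$disp
    levs <- levels(dat$cohort_id)
    sd_fun <- function(L, cohort) {
      eta <- disp_beta["(Intercept)"] + disp_beta["total_length_mm"] * L
      if (!identical(cohort, "marginal")) {
        nm <- paste0("cohort_id", cohort)
        if (nm %in% names(disp_beta)) eta <- eta + disp_beta[nm]
      } else {
        extra <- disp_beta[paste0("cohort_id", levs[-1])]
        extra[is.na(extra)] <- 0
        eta <- eta + mean(c(0, extra))
      }
      sqrt(exp(as.numeric(eta)))
    }
    cohort_sd <- sqrt(glmmTMB::VarCorr(fit)$cond$cohort_id[1, 1])
    engine <- "glmmTMB"
    model <- fit
  }

  ages <- dat$post_settlement_age_days
  obj <- structure(list(
    fixed_coefficients = stats::setNames(raw, c("b0", "b1", "b2", "b3")),
    cohort_effects = eff,
    cohort_sd = cohort_sd,
    sd_fun = sd_fun,
    cohorts = cohorts,
    length_range = length_range,
    age_range = range(ages),
    mean_pld_days = mean_pld_days,
    n = nrow(dat),
    engine = engine,
    fallback_reason = fallback_reason,
    model = model), class = "age_length_fit")
  # diagnostic: predicted mean age should be non-decreasing over the
  # observed length range (cubics can wiggle); violations are flagged
  g <- seq(length_range[1], length_range[2], length.out = 200)
  mu <- predict_age(obj, g, "marginal")$age_days
  obj$monotone <- all(diff(mu) > -1e-8)
  if (!obj$monotone) {
    warning("fitted mean age is not monotone in length over the observed range")
  }
  obj
}

#' @export
print.age_length_fit <- function(x, ...) {
  cat(sprintf(
    "<age_length_fit [%s]: n=%d aged fish, %d cohorts (sd %.2f d)>\n",
    x$engine, x$n, length(x$cohort_effects), x$cohort_sd))
  cat("  mean age = b0 + b1*L + b2*L^2 + b3*L^3, raw-scale coefficients:\n")
  print(signif(x$fixed_coefficients, 6))
  invisible(x)
}

#' Assign a collection date to a recruitment cohort
#'
#' A collection date is mapped to the cohort whose plausible collection
#' interval contains it: the cohort hatch window shifted forward by the
#' minimum and maximum observed post-settlement age plus the mean PLD. Ties
#' go to the cohort with the nearest window midpoint, the earlier cohort
#' when equidistant. Dates outside every interval return `"marginal"`.
#'
#' @param collection_date a `Date` vector.
#' @param cohorts a [define_cohorts()] table.
#' @param fit an [fit_age_length()] object (supplies the observed age range
#'   and mean PLD that define the plausible intervals).
#' @return character vector of cohort ids or `"marginal"`.
#' @export
assign_cohort <- function(collection_date, cohorts, fit) {
  stopifnot(nrow(cohorts) >= 1)
  shift_lo <- fit$age_range[1] + fit$mean_pld_days
  shift_hi <- fit$age_range[2] + fit$mean_pld_days
  lo <- as.numeric(cohorts$start_date) + shift_lo
  hi <- as.numeric(cohorts$end_date) + shift_hi
  mid <- (lo + hi) / 2
  vapply(as.numeric(as_date(collection_date)), function(d) {
    hit <- which(d >= lo & d <= hi)
    if (length(hit) == 0) return("marginal")
    if (length(hit) > 1) hit <- hit[order(abs(d - mid[hit]), hit)][1]
    cohorts$cohort_id[hit]
  }, character(1))
}

#' Predict post-settlement age from total length
#'
#' Cohort-conditional predictions add that cohort's random intercept;
#' `"marginal"` uses the fixed cubic alone (cohort effects average to zero).
#' The 95% interval comes from the fitted log-linear variance model at that
#' length and cohort. Lengths outside the observed range +/- 10% refuse to
#' predict: cubics diverge under extrapolation.
#'
#' @param fit an [fit_age_length()] object.
#' @param total_length_mm numeric vector of lengths (mm).
#' @param cohort_id a single cohort id, or `"marginal"`.
#' @return data.frame with `age_days`, `lwr`, `upr`.
#' @export
predict_age <- function(fit, total_length_mm, cohort_id = "marginal") {
  stopifnot(inherits(fit, "age_length_fit"), length(cohort_id) == 1L)
  span <- diff(fit$length_range)
  ok <- total_length_mm >= fit$length_range[1] - 0.1 * span &
    total_length_mm <= fit$length_range[2] + 0.1 * span
  if (!all(ok)) {
    stop("length(s) outside the observed range +/-10%: ",
         paste(signif(total_length_mm[!ok], 4), collapse = ", "),
         " (no extrapolation)")
  }
  b <- fit$fixed_coefficients
  mu <- b[1] + b[2] * total_length_mm + b[3] * total_length_mm^2 +
    b[4] * total_length_mm^3
  if (!identical(cohort_id, "marginal")) {
    if (!cohort_id %in% names(fit$cohort_effects)) {
      stop("unknown cohort id: ", cohort_id)
    }
    mu <- mu + fit$cohort_effects[[cohort_id]]
  }
  sdv <- fit$sd_fun(total_length_mm, cohort_id)
  data.frame(age_days = as.numeric(mu),
             lwr = as.numeric(mu) - 1.96 * sdv,
             upr = as.numeric(mu) + 1.96 * sdv)
}

#' Impute ages of non-aged fish from the age-length fit
#'
#' Non-aged fish are assigned to cohorts by collection date
#' ([assign_cohort()]) and their post-settlement age predicted from total
#' length. Fish whose length falls outside the fit's supported range are
#' left un-imputed and counted in the report. Fish assigned to a cohort with
#' no aged members are dropped from imputation and flagged.
#'
#' @param fish full fish table (aged rows keep their measured ages).
#' @param fit an [fit_age_length()] object.
#' @return the table with imputed `post_settlement_age_days` for non-aged
#'   rows and an `imputed` flag; attribute `imputation_report` counts
#'   imputed / out-of-range / orphan-cohort fish.
#' @export
impute_ages <- function(fish, fit) {
  target <- which(is.na(fish$post_settlement_age_days))
  fish$imputed <- FALSE
  out_of_range <- 0L
  orphan <- 0L
  known <- names(fit$cohort_effects)
  for (i in target) {
    cid <- assign_cohort(fish$collection_date[i], fit$cohorts, fit)
    if (cid != "marginal" && !cid %in% known) {
      orphan <- orphan + 1L
      next
    }
    pred <- tryCatch(predict_age(fit, fish$total_length_mm[i], cid),
                     error = function(e) NULL)
    if (is.null(pred)) {
      out_of_range <- out_of_range + 1L
      next
    }
    fish$post_settlement_age_days[i] <- max(pred$age_days, 1)
    fish$imputed[i] <- TRUE
  }
  attr(fish, "imputation_report") <- list(
    n_imputed = sum(fish$imputed), n_out_of_range = out_of_range,
    n_orphan_cohort = orphan)
  fish
}
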