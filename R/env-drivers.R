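# Environmental covariates on the 5-day spawning bins: lunar illumination
# with the AEST shift, 8-day SST averages mapped to bins, and the
# SST-by-month Tweedie smooth with AICc covariate screening and concurvity
# checks.

# 8-day block average of a daily SST series, emulating satellite composites;
# returns block start dates and means.
sst_8day_composite <- function(env) {
  env <- env[order(env$date), ]
  block <- floor(as.numeric(env$date - env$date[1]) / 8)
  starts <- env$date[1] + 8 * sort(unique(block))
  means <- tapply(env$sst_C, block, mean, na.rm = TRUE)
  data.frame(start_date = starts, sst_C = as.numeric(means))
}

#' Build environmental covariate bins aligned with a spawning series
#'
#' For each 5-day spawning bin: lunar illumination is averaged over the
#' bin's days (daily values at local midnight under the +10 h convention);
#' SST is the 8-day composite average whose window contains the bin
#' midpoint, with gaps linearly interpolated up to `max_gap_days`; rainfall
#' is summed. Bins whose SST gap exceeds the limit are flagged and excluded
#' from modelling.
#'
#' @param env daily environmental data.frame (`date`, `sst_C`,
#'   `rainfall_mm`, optionally `flood_height_m`).
#' @param series a [bin_hatch_dates()] spawning series.
#' @param shift_hours lunar local-time shift (default 10).
#' @param max_gap_days maximum SST gap to interpolate across (default 16).
#' @return data.frame of class `env_bins`: one row per 5-day bin with
#'   `start_date`, `lunar_illumination`, `sst_C`, `rainfall_mm`,
#'   `flood_height_m`, `month`, `year_label`, `spawn_count`, `flagged`.
#' @export
build_env_bins <- function(env, series, shift_hours = 10,
                           max_gap_days = 16) {
  stopifnot(inherits(series, "spawning_series"))
  bins <- series$bins
  need_start <- bins$start_date[1]
  need_end <- bins$start_date[nrow(bins)] + bins$n_days[nrow(bins)] - 1
  if (min(env$date) > need_start || max(env$date) < need_end) {
    stop("environmental series does not cover the spawning bins")
  }
  comp <- sst_8day_composite(env[!is.na(env$sst_C), ])
  mids <- as.numeric(bins$start_date) + bins$n_days / 2
  comp_mid <- as.numeric(comp$start_date) + 4
  sst <- stats::approx(comp_mid, comp$sst_C, xout = mids, rule = 2)$y
  # distance from each bin midpoint to the nearest observed composite
  gap <- vapply(mids, function(m) min(abs(m - comp_mid)), numeric(1))
  flagged <- gap > max_gap_days
  illum <- vapply(seq_len(nrow(bins)), function(i) {
    days <- bins$start_date[i] + seq_len(bins$n_days[i]) - 1
    mean(lunar_illumination(days, shift_hours = shift_hours))
  }, numeric(1))
  rain <- vapply(seq_len(nrow(bins)), function(i) {
    days <- bins$start_date[i] + seq_len(bins$n_days[i]) - 1
    sum(env$rainfall_mm[env$date %in% days], na.rm = TRUE)
  }, numeric(1))
  flood <- if ("flood_height_m" %in% names(env)) {
    vapply(seq_len(nrow(bins)), function(i) {
      days <- bins$start_date[i] + seq_len(bins$n_days[i]) - 1
      mean(env$flood_height_m[env$date %in% days], na.rm = TRUE)
    }, numeric(1))
  } else NA_real_
  out <- data.frame(
    start_date = bins$start_date,
    lunar_illumination = illum,
    sst_C = sst,
    rainfall_mm = rain,
    flood_height_m = flood,
    month = as.integer(format(bins$start_date, "%m")),
    year_label = series$year,
    spawn_count = bins$count,
    flagged = flagged)
  if (any(flagged)) {
    message("build_env_bins: ", sum(flagged),
            " bin(s) flagged for SST gaps > ", max_gap_days, " days")
  }
  structure(out, class = c("env_bins", "data.frame"))
}

#' Fit the environmental Tweedie smooth with covariate screening
#'
#' Fits `count = exp(b0 + s(SST, month) + s(year))` with Tweedie errors to
#' the pooled 5-day bins: a tensor-product interaction between a continuous
#' SST smooth and a cyclic month smooth, plus a year-level random effect.
#' Candidate models adding lunar illumination and rainfall smooths are
#' compared by AICc and reported in a selection table; the lowest-AICc model
#' is returned. Pairwise concurvity between terms of the selected model is
#' computed and terms above `concurvity_flag` are flagged (high concurvity
#' is the smooth-model analogue of collinearity). Flood height is accepted
#' as a candidate only on request: it typically tracks SST and season.
#'
#' Covariates are screened by AICc with a parsimony tie-break: among
#' candidates within `aicc_tie` of the lowest AICc (default 2, the usual
#' equivalence margin), the one with the fewest terms is selected. Fully
#' penalized-out covariates cost almost no AICc, so a strict minimum would
#' pick noise terms at random; the tie-break is what operationalizes
#' "not an important explanatory variable, excluded".
#'
#' @param env_bins pooled [build_env_bins()] rows (>= 2 distinct years).
#' @param include_flood also consider a flood-height smooth (default FALSE).
#' @param k_sst,k_month tensor marginal basis dimensions.
#' @param p_grid Tweedie power grid.
#' @param concurvity_flag pairwise concurvity threshold (default 0.7).
#' @param aicc_tie AICc equivalence margin for the parsimony tie-break.
#' @return object of class `env_smooth_fit`: the selected `mgcv::gam`, the
#'   AICc `selection` table, `concurvity` matrix and `flagged_terms`.
#' @export
fit_env_smooth <- function(env_bins, include_flood = FALSE,
                           k_sst = 5, k_month = 6,
                           p_grid = seq(1.05, 1.95, length.out = 10),
                           concurvity_flag = 0.7, aicc_tie = 2) {
  dat <- as.data.frame(env_bins[!env_bins$flagged, ])
  if (length(unique(dat$year_label)) < 2) {
    stop("need >= 2 years of environmental bins")
  }
  dat$year_f <- factor(dat$year_label)
  dat$count <- dat$spawn_count
  base <- sprintf(
    "count ~ te(sst_C, month, bs = c('tp', 'cc'), k = c(%d, %d)) + s(year_f, bs = 're')",
    k_sst, k_month)
  cands <- c(
    null = "count ~ s(year_f, bs = 're')",
    sst_month = base,
    plus_lunar = paste(base, "+ s(lunar_illumination, k = 5)"),
    plus_rain = paste(base, "+ s(rainfall_mm, k = 5)"))
  if (include_flood) {
    cands <- c(cands, plus_flood = paste(base, "+ s(flood_height_m, k = 5)"))
  }
  knots <- list(month = c(0.5, 12.5))
  fit_at <- function(fstr, p) {
    tryCatch(
      suppressWarnings(
        mgcv::gam(stats::as.formula(fstr),
                  family = mgcv::Tweedie(p = p, link = "log"),
                  data = dat, knots = knots, method = "REML",
                  select = TRUE, control = mgcv::gam.control(maxit = 50))),
      error = function(e) NULL)
  }
  # profile the Tweedie power once on the base SST-by-month model, then
  # compare candidates at that power so AICc differences reflect the mean
  # structure, not the power grid
  base_scores <- vapply(p_grid, function(p) {
    fit <- fit_at(base, p)
    if (is.null(fit)) Inf else aicc(fit)
  }, numeric(1))
  p_best <- if (all(!is.finite(base_scores))) {
    stats::median(p_grid)
  } else p_grid[which.min(base_scores)]
  fits <- lapply(cands, function(fstr) {
    fit <- fit_at(fstr, p_best)
    if (is.null(fit)) NULL else list(fit = fit, aicc = aicc(fit), p = p_best)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no environmental model converged")
  sel <- data.frame(model = names(cands)[ok],
                    formula = unname(cands[ok]),
                    n_terms = match(names(cands)[ok], names(cands)),
                    aicc = vapply(fits[ok], `[[`, numeric(1), "aicc"),
                    tweedie_p = vapply(fits[ok], `[[`, numeric(1), "p"))
  sel <- sel[order(sel$aicc), ]
  rownames(sel) <- NULL
  # parsimony tie-break: simplest candidate within aicc_tie of the minimum
  eligible <- sel[sel$aicc <= sel$aicc[1] + aicc_tie, ]
  chosen_name <- eligible$model[which.min(eligible$n_terms)]
  chosen <- fits[[chosen_name]]
  conc <- tryCatch({
    cm <- mgcv::concurvity(chosen$fit, full = FALSE)$estimate
    cm
  }, error = function(e) NULL)
  flagged_terms <- character(0)
  if (!is.null(conc) && nrow(conc) > 1) {
    off <- conc
    diag(off) <- 0
    flagged_terms <- rownames(off)[apply(off, 1, max) > concurvity_flag]
  }
  sm <- summary(chosen$fit)
  structure(list(
    gam = chosen$fit,
    model = chosen_name,
    selection = sel,
    aicc_tie = aicc_tie,
    tweedie_power_p = chosen$p,
    aicc = chosen$aicc,
    deviance_explained = sm$dev.expl,
    concurvity = conc,
    flagged_terms = flagged_terms,
    concurvity_flag = concurvity_flag), class = "env_smooth_fit")
}

#' @export
print.env_smooth_fit <- function(x, ...) {
  cat(sprintf(
    "<env_smooth_fit: selected '%s', p=%.3f, AICc %.1f, deviance explained %.1f%%>\n",
    x$model, x$tweedie_power_p, x$aicc, 100 * x$deviance_explained))
  if (length(x$flagged_terms) > 0) {
    cat("  concurvity >", x$concurvity_flag, "for:",
        paste(x$flagged_terms, collapse = ", "), "\n")
  }
  invisible(x)
}
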