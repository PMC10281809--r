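# New-moon-anchored closure windows in the October-December season, the
# capture-proportion statistic against predicted spawning activity, and the
# Beta mixed model of capture vs closure number and duration.

season_range <- function(year) {
  c(as.Date(sprintf("%d-10-01", year)), as.Date(sprintf("%d-12-31", year)))
}

#' Build new-moon-anchored closure windows
#'
#' Closure windows are centred on new-moon dates (9-day: moon +/- 4 days;
#' 5-day: moon +/- 2 days), clipped to the October 1 - December 31 season.
#' When fewer closures than new moons are requested the earliest moons are
#' used (October onward). Overlapping windows are merged with a warning.
#'
#' @param moons `Date` vector of new-moon dates (see [new_moons()]).
#' @param duration_days window length in days (odd; typically 5 or 9).
#' @param n_closures number of windows to place (<= length(moons)).
#' @param season length-2 `Date` vector bounding the closed season.
#' @param anchor_offset_days shift of the window centre from the new moon
#'   (default 0: centred).
#' @return data.frame of class `closure_windows`: `start_date`, `end_date`,
#'   `duration_days`, `anchor_new_moon`.
#' @export
#' @examples
#' m <- new_moons(as.Date("2021-10-01"), as.Date("2021-12-31"))
#' make_closures(m, duration_days = 5, n_closures = 2,
#'               season = as.Date(c("2021-10-01", "2021-12-31")))
make_closures <- function(moons, duration_days, n_closures,
                          season, anchor_offset_days = 0) {
  moons <- sort(as_date(moons))
  season <- as_date(season)
  stopifnot(duration_days >= 1, n_closures >= 1,
            n_closures <= length(moons))
  moons <- moons[seq_len(n_closures)]
  half <- (duration_days - 1) %/% 2
  centre <- moons + anchor_offset_days
  start <- pmax(centre - half, season[1])
  end <- pmin(centre + (duration_days - 1 - half), season[2])
  w <- data.frame(start_date = start, end_date = end,
                  anchor_new_moon = moons)
  w <- w[order(w$start_date), ]
  # merge overlaps
  merged <- w[1, , drop = FALSE]
  overlapped <- FALSE
  for (i in seq_len(nrow(w))[-1]) {
    last <- nrow(merged)
    if (w$start_date[i] <= merged$end_date[last] + 0) {
      overlapped <- TRUE
      merged$end_date[last] <- max(merged$end_date[last], w$end_date[i])
    } else {
      merged <- rbind(merged, w[i, ])
    }
  }
  if (overlapped) warning("overlapping closure windows merged")
  merged$duration_days <-
    as.numeric(merged$end_date - merged$start_date) + 1
  rownames(merged) <- NULL
  out <- structure(merged[, c("start_date", "end_date", "duration_days",
                              "anchor_new_moon")],
                   class = c("closure_windows", "data.frame"))
  # the requested policy, kept separate from realized (possibly clipped or
  # merged) window widths
  attr(out, "policy") <- list(duration_days = duration_days,
                              n_closures = n_closures)
  out
}

#' Proportion of spawning activity captured by closure windows
#'
#' Evaluates the daily spawning-activity curve over the October-December
#' season and computes the fraction of total activity that falls on closed
#' days, alongside the uniform-spawning expectation
#' `closed_days / season_days`.
#'
#' @param daily_activity either a function mapping `Date` to non-negative
#'   activity, or a data.frame with `date` and `activity` columns covering
#'   the season (e.g. from [predict_activity()]).
#' @param windows a [make_closures()] table.
#' @param season length-2 `Date` vector (default: the Oct 1 - Dec 31 season
#'   of the first window's year).
#' @return one-row data.frame of class `capture_result`: `year_label`,
#'   `n_closures`, `duration_days`, `closed_days`, `captured_proportion`,
#'   `expected_uniform`.
#' @export
capture_proportion <- function(daily_activity, windows, season = NULL) {
  stopifnot(nrow(windows) >= 1)
  if (is.null(season)) {
    season <- season_range(as.integer(format(windows$start_date[1], "%Y")))
  }
  season <- as_date(season)
  days <- seq(season[1], season[2], by = "day")
  act <- if (is.function(daily_activity)) {
    daily_activity(days)
  } else {
    stopifnot(all(c("date", "activity") %in% names(daily_activity)))
    idx <- match(days, daily_activity$date)
    if (anyNA(idx)) stop("daily_activity does not cover the season")
    daily_activity$activity[idx]
  }
  if (any(act < 0)) stop("daily activity must be non-negative")
  total <- sum(act)
  if (total <= 0) stop("all-zero activity over the season: capture undefined")
  closed <- rep(FALSE, length(days))
  for (i in seq_len(nrow(windows))) {
    closed <- closed | (days >= windows$start_date[i] &
                          days <= windows$end_date[i])
  }
  policy <- attr(windows, "policy")
  structure(data.frame(
    year_label = austral_year(season[1]),
    n_closures = if (!is.null(policy)) policy$n_closures else nrow(windows),
    duration_days = if (!is.null(policy)) policy$duration_days else
      max(windows$duration_days),
    closed_days = sum(closed),
    captured_proportion = sum(act[closed]) / total,
    expected_uniform = sum(closed) / length(days)),
    class = c("capture_result", "data.frame"))
}

#' Daily activity from raw binned counts
#'
#' Spreads each 5-day bin count evenly over its days — the diagnostic
#' alternative to the model-predicted activity curve.
#'
#' @param series a [bin_hatch_dates()] object.
#' @return data.frame `date`, `activity` (counts per bin scale).
#' @export
raw_daily_activity <- function(series) {
  bins <- series$bins
  do.call(rbind, lapply(seq_len(nrow(bins)), function(i) {
    data.frame(date = bins$start_date[i] + seq_len(bins$n_days[i]) - 1,
               activity = bins$count[i] / bins$n_days[i] * 5)
  }))
}

#' Evaluate a grid of closure policies against fitted spawning curves
#'
#' For each year's fitted spawning smooth and each combination of closure
#' duration and count, places new-moon-anchored windows in that year's
#' October-December season and computes the captured proportion of
#' predicted spawning activity. `activity = "raw"` uses the raw binned
#' counts instead of the fitted curve, as a diagnostic.
#'
#' @param fits_by_year named list (austral-year label -> `smooth_fit`).
#' @param durations closure durations in days (default `c(5, 9)`).
#' @param counts numbers of closures (default `1:3`).
#' @param activity `"model"` (fitted curve, the default) or `"raw"`
#'   (observed bin counts spread over days).
#' @return data.frame of stacked [capture_proportion()] rows with
#'   `duration_days` and `n_closures` as requested.
#' @export
evaluate_closures <- function(fits_by_year, durations = c(5, 9),
                              counts = 1:3,
                              activity = c("model", "raw")) {
  activity <- match.arg(activity)
  rows <- list()
  for (y in names(fits_by_year)) {
    fit <- fits_by_year[[y]]
    season <- season_range(as.integer(y))
    act <- if (activity == "model") {
      predict_activity(fit)
    } else {
      raw_daily_activity(fit$series)
    }
    if (min(act$date) > season[1] || max(act$date) < season[2]) next
    moons <- new_moons(season[1], season[2])
    for (d in durations) {
      for (k in counts) {
        if (k > length(moons)) next
        w <- make_closures(moons, d, k, season)
        cp <- capture_proportion(act, w, season)
        cp$n_closures <- k
        cp$duration_days <- d
        rows[[length(rows) + 1]] <- cp
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Beta mixed model of captured proportion vs closure design
#'
#' Models the per-year captured proportions against closure duration and
#' closure count with a Beta likelihood (logit mean link) and a year-level
#' random intercept. Proportions at the 0/1 boundary are shrunk by the
#' standard `(y * (n - 1) + 0.5) / n` transform. The duration-by-count
#' interaction is tested first and dropped when non-significant. Closure
#' -count contrasts are multiplicity-adjusted (Tukey); the duration effect
#' is reported as the 9-day : 5-day capture ratio on the response scale.
#'
#' @param results stacked [capture_proportion()] rows across years with at
#'   least two levels of `duration_days` and of `n_closures`.
#' @param interaction_alpha level for dropping the interaction (default
#'   0.05).
#' @return object of class `capture_model`: the `glmmTMB` fit, `engine`
#'   ("glmmTMB" or "betareg-fixed" fallback), `interaction_p`,
#'   `duration_ratio`, `count_contrasts` (Tukey-adjusted emmeans table).
#' @export
fit_capture_model <- function(results, interaction_alpha = 0.05) {
  dat <- as.data.frame(results)
  stopifnot(length(unique(dat$duration_days)) >= 2,
            length(unique(dat$n_closures)) >= 2)
  n <- nrow(dat)
  dat$y <- (dat$captured_proportion * (n - 1) + 0.5) / n
  dat$duration_f <- factor(dat$duration_days)
  dat$count_f <- factor(dat$n_closures)
  dat$year_f <- factor(dat$year_label)

  if (stats::var(dat$y) == 0) {
    # all proportions identical after the transform: slopes are exactly
    # zero and the Beta precision diverges, so report the degenerate fit
    # directly instead of pushing a flat likelihood through the optimizer
    cl <- utils::combn(levels(dat$count_f), 2)
    contrasts <- data.frame(
      contrast = apply(cl, 2, function(p) {
        paste0("count_f", p[1], " - count_f", p[2])
      }),
      estimate = 0, SE = NA_real_, df = NA_real_, z.ratio = NA_real_,
      p.value = 1)
    return(structure(list(
      fit = NULL, engine = "degenerate",
      interaction_p = NA_real_, interaction_kept = FALSE,
      duration_ratio = 1,
      duration_test = data.frame(contrast = "duration", estimate = 0,
                                 p.value = 1),
      count_contrasts = contrasts,
      data = dat), class = "capture_model"))
  }

  fit_with <- function(formula) {
    f <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(formula, data = dat,
                                        family = glmmTMB::beta_family())),
      error = function(e) NULL)
    if (!is.null(f) && !isTRUE(f$sdr$pdHess)) f <- NULL
    f
  }
  engine <- "glmmTMB"
  full <- fit_with(y ~ duration_f * count_f + (1 | year_f))
  main <- fit_with(y ~ duration_f + count_f + (1 | year_f))
  if (is.null(main)) {
    engine <- "betareg-fixed"
    message("fit_capture_model: mixed Beta fit failed to converge; ",
            "falling back to fixed-effects Beta regression")
    full <- fit_with(y ~ duration_f * count_f)
    main <- fit_with(y ~ duration_f + count_f)
    if (is.null(main)) stop("Beta regression failed to converge")
  }
  interaction_p <- if (!is.null(full)) {
    stats::anova(main, full)$`Pr(>Chisq)`[2]
  } else NA_real_
  use_interaction <- is.finite(interaction_p) &&
    interaction_p < interaction_alpha
  fit <- if (use_interaction) full else main

  emd <- emmeans::emmeans(fit, ~ duration_f, type = "response")
  emd_df <- as.data.frame(emd)
  resp_col <- intersect(c("response", "emmean"), names(emd_df))[1]
  lev <- as.numeric(as.character(emd_df$duration_f))
  ratio <- emd_df[[resp_col]][which.max(lev)] /
    emd_df[[resp_col]][which.min(lev)]
  emc <- emmeans::emmeans(fit, ~ count_f)
  contrasts <- as.data.frame(emmeans::contrast(emc, method = "pairwise",
                                               adjust = "tukey"))
  dur_test <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(fit, ~ duration_f), method = "pairwise",
    adjust = "tukey"))
  structure(list(
    fit = fit, engine = engine,
    interaction_p = interaction_p,
    interaction_kept = use_interaction,
    duration_ratio = as.numeric(ratio),
    duration_test = dur_test,
    count_contrasts = contrasts,
    data = dat), class = "capture_model")
}

#' @export
print.capture_model <- function(x, ...) {
  cat(sprintf(
    "<capture_model [%s]: 9:5 duration capture ratio %.2f; interaction p=%.3g (%s)>\n",
    x$engine, x$duration_ratio, x$interaction_p,
    if (x$interaction_kept) "kept" else "dropped"))
  cat("  closure-count contrasts (Tukey):\n")
  print(x$count_contrasts, digits = 3)
  invisible(x)
}
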