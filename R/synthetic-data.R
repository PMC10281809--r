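# Synthetic field collections. The generator emulates the statistical
# structure the downstream analysis assumes: multi-cohort spawning pulses
# 1-4 months wide, monotone juvenile growth over 23-248 mm, replicate ageing
# error, a ~43% aged fraction, and sinusoidal SST with lunar cycles.

#' Spawning regime: a mixture intensity of hatch dates
#'
#' A spawning regime is a mixture of truncated-normal pulses in time (one per
#' recruitment cohort) plus a uniform background rate, restricted to a closed
#' date range. Pulse spreads of roughly 10-30 days reproduce cohorts spanning
#' one to four months.
#'
#' @param components a data.frame with columns `peak_date` (Date),
#'   `spread_days` (> 0) and `weight` (> 0); may have zero rows.
#' @param background_rate non-negative uniform background intensity
#'   (relative weight of spawns spread evenly over the range).
#' @param date_range length-2 `Date` vector, closed interval.
#' @return an object of class `spawning_regime`.
#' @export
#' @examples
#' spawning_regime(
#'   data.frame(peak_date = as.Date("2020-12-01"), spread_days = 15,
#'              weight = 1),
#'   background_rate = 0.05,
#'   date_range = as.Date(c("2020-07-01", "2021-06-30")))
spawning_regime <- function(components, background_rate = 0,
                            date_range) {
  if (is.null(components)) {
    components <- data.frame(peak_date = as.Date(character()),
                             spread_days = numeric(), weight = numeric())
  }
  stopifnot(is.data.frame(components),
            all(c("peak_date", "spread_days", "weight") %in%
                  names(components)))
  components$peak_date <- as_date(components$peak_date)
  date_range <- as_date(date_range)
  stopifnot(length(date_range) == 2L, date_range[1] <= date_range[2])
  if (nrow(components) > 0) {
    stopifnot(all(is.finite(components$spread_days)),
              all(components$spread_days > 0),
              all(is.finite(components$weight)),
              all(components$weight > 0))
  }
  stopifnot(is.finite(background_rate), background_rate >= 0)
  structure(list(components = components,
                 background_rate = background_rate,
                 date_range = date_range),
            class = "spawning_regime")
}

#' @export
print.spawning_regime <- function(x, ...) {
  cat(sprintf("<spawning_regime: %d pulse(s), background %.3g, %s to %s>\n",
              nrow(x$components), x$background_rate,
              format(x$date_range[1]), format(x$date_range[2])))
  invisible(x)
}

#' Juvenile growth model (von Bertalanffy)
#'
#' Total length at post-settlement age `a` days is
#' `Linf - (Linf - L0) * exp(-K * a)` plus Gaussian noise. Over the juvenile
#' range (23-248 mm) the curve is near-linear and strictly increasing, so it
#' is invertible for the age-length stage.
#'
#' @param length_at_settlement_mm length at age 0 post-settlement (mm).
#' @param asymptotic_length_mm von Bertalanffy asymptote `Linf` (mm).
#' @param growth_rate_per_day von Bertalanffy `K` (per day).
#' @param length_noise_sd_mm sd of additive length noise (mm).
#' @return an object of class `growth_model`.
#' @export
growth_model <- function(length_at_settlement_mm = 23,
                         asymptotic_length_mm = 650,
                         growth_rate_per_day = 0.001,
                         length_noise_sd_mm = 4) {
  stopifnot(length_at_settlement_mm > 0,
            asymptotic_length_mm > length_at_settlement_mm,
            growth_rate_per_day > 0,
            length_noise_sd_mm >= 0)
  structure(list(length_at_settlement_mm = length_at_settlement_mm,
                 asymptotic_length_mm = asymptotic_length_mm,
                 growth_rate_per_day = growth_rate_per_day,
                 length_noise_sd_mm = length_noise_sd_mm),
            class = "growth_model")
}

#' Mean length at post-settlement age under a growth model
#' @param growth a [growth_model()].
#' @param age_days post-settlement age in days (vector).
#' @return mean total length in mm.
#' @export
growth_length_at_age <- function(growth, age_days) {
  with(growth, asymptotic_length_mm -
         (asymptotic_length_mm - length_at_settlement_mm) *
         exp(-growth_rate_per_day * age_days))
}

#' Invert a growth model: post-settlement age at mean length
#' @param growth a [growth_model()].
#' @param length_mm total length in mm (must be below the asymptote).
#' @return age in days.
#' @export
growth_age_at_length <- function(growth, length_mm) {
  stopifnot(all(length_mm < growth$asymptotic_length_mm))
  with(growth,
       -log((asymptotic_length_mm - length_mm) /
              (asymptotic_length_mm - length_at_settlement_mm)) /
         growth_rate_per_day)
}

#' Replicate-ageing error model
#'
#' Each of the three replicate increment counts is the true post-settlement
#' age perturbed by Gaussian error with coefficient of variation `count_cv`,
#' rounded to a whole increment. Pelagic larval duration (PLD) is drawn
#' per fish from `N(pld_mean_days, pld_sd_days^2)`; defaults reproduce the
#' study population of 27.9 +/- 1.6 days.
#'
#' The default `count_cv = 0.03` makes the 10%-of-median QC rule reject a
#' small minority of fish, the behaviour implied by a rule that exists but
#' rarely fires.
#'
#' @param count_cv coefficient of variation of a replicate count.
#' @param pld_mean_days,pld_sd_days PLD distribution parameters (days).
#' @return an object of class `ageing_error_model`.
#' @export
ageing_error_model <- function(count_cv = 0.03, pld_mean_days = 27.9,
                               pld_sd_days = 1.6) {
  stopifnot(count_cv >= 0, pld_mean_days > 0, pld_sd_days >= 0)
  structure(list(count_cv = count_cv, pld_mean_days = pld_mean_days,
                 pld_sd_days = pld_sd_days),
            class = "ageing_error_model")
}

# Truncated-normal sampler by inverse CDF; bounds in days relative to mean.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Sample hatch dates from a spawning regime
#'
#' Draws calendar hatch dates from the mixture intensity: truncated-normal
#' pulses (truncation at the regime's date range) plus a uniform background.
#' Identical seeds give identical draws.
#'
#' @param regime a [spawning_regime()].
#' @param n number of hatch dates (>= 1).
#' @param seed integer seed.
#' @return a `Date` vector of length `n`, unordered.
#' @export
sample_hatch_dates <- function(regime, n, seed) {
  stopifnot(inherits(regime, "spawning_regime"), n >= 1)
  comp <- regime$components
  if (nrow(comp) == 0 && regime$background_rate <= 0) {
    stop("empty spawning regime: no components and zero background rate")
  }
  r0 <- as.numeric(regime$date_range[1])
  r1 <- as.numeric(regime$date_range[2]) + 1  # closed interval of whole days
  with_seed(seed, {
    span <- r1 - r0
    w <- c(comp$weight, regime$background_rate * span)
    idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    days <- numeric(n)
    bg <- idx > nrow(comp)
    if (any(bg)) days[bg] <- stats::runif(sum(bg), r0, r1)
    for (j in seq_len(nrow(comp))) {
      sel <- idx == j
      if (!any(sel)) next
      days[sel] <- rtruncnorm(sum(sel), as.numeric(comp$peak_date[j]) + 0.5,
                              comp$spread_days[j], r0, r1)
    }
    as.Date(floor(days), origin = "1970-01-01")
  })
}

#' Realize fish records from hatch dates
#'
#' Given true hatch dates, grows each fish forward and assigns it to the
#' first sampling trip at which it has settled (post-settlement age > PLD
#' has elapsed since hatching) and is still within the 250 mm collection
#' limit. Three replicate increment counts with CV `error$count_cv` are
#' recorded for a Bernoulli-thinned aged fraction of fish (stratified by
#' trip); a subset of aged fish also carries a pre-settlement increment
#' count (the PLD read from the otolith core). True hatch date and true age
#' are carried in `true_*` columns for testing only; analysis stages never
#' read them.
#'
#' @param hatch_dates `Date` vector of true hatch dates.
#' @param growth a [growth_model()].
#' @param error an [ageing_error_model()].
#' @param trip_dates `Date` vector of collection-trip dates.
#' @param seed integer seed.
#' @param aged_fraction fraction of collected fish that are aged
#'   (default 0.43, the study-scale value).
#' @param pld_read_fraction fraction of aged fish whose otolith core is also
#'   read for PLD (default 0.1).
#' @return a data.frame of fish records (one row per collected fish) with
#'   attribute `dropped` counting fish no trip admitted.
#' @export
realize_fish <- function(hatch_dates, growth, error, trip_dates, seed,
                         aged_fraction = 0.43, pld_read_fraction = 0.1) {
  hatch_dates <- as_date(hatch_dates)
  trip_dates <- sort(as_date(trip_dates))
  stopifnot(inherits(growth, "growth_model"),
            inherits(error, "ageing_error_model"),
            length(trip_dates) >= 1,
            all(trip_dates > min(hatch_dates)),
            aged_fraction >= 0, aged_fraction <= 1)
  n <- length(hatch_dates)
  with_seed(seed, {
    pld <- stats::rnorm(n, error$pld_mean_days, error$pld_sd_days)
    pld <- pmax(1, pld)
    # first trip where the fish has settled and is still <= 250 mm
    rows <- vector("list", n)
    dropped <- 0L
    for (i in seq_len(n)) {
      assigned <- NA
      for (td in as.numeric(trip_dates)) {
        age_post <- td - as.numeric(hatch_dates[i]) - pld[i]
        # at least one post-settlement increment must exist to be countable
        if (age_post < 1) next
        len_mean <- growth_length_at_age(growth, age_post)
        if (len_mean <= 250) {
          assigned <- td
          break
        }
      }
      if (is.na(assigned)) {
        dropped <- dropped + 1L
        next
      }
      age_post <- assigned - as.numeric(hatch_dates[i]) - pld[i]
      len <- growth_length_at_age(growth, age_post) +
        stats::rnorm(1, 0, growth$length_noise_sd_mm)
      len <- min(max(len, 5), 250)
      rows[[i]] <- data.frame(
        collection_date = as.Date(assigned, origin = "1970-01-01"),
        total_length_mm = len,
        true_age_days = age_post,
        true_pld_days = pld[i],
        true_hatch_date = hatch_dates[i])
    }
    fish <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(fish)) {
      stop("no trip admitted any fish (", dropped, " dropped)")
    }
    fish <- fish[order(fish$collection_date, fish$true_hatch_date), ]
    nf <- nrow(fish)
    fish$fish_id <- sprintf("F%05d", seq_len(nf))
    # fork length and weight: simple allometries with noise, plumbing only
    fish$fork_length_mm <- round(fish$total_length_mm * 0.93 +
                                   stats::rnorm(nf, 0, 2), 1)
    fish$weight_g <- round(exp(-11.3 + 3.0 * log(fish$total_length_mm)) *
                             exp(stats::rnorm(nf, 0, 0.08)), 1)
    # aged subset: Bernoulli thinning stratified by trip
    fish$aged <- FALSE
    for (td in unique(fish$collection_date)) {
      sel <- which(fish$collection_date == td)
      fish$aged[sel] <- stats::runif(length(sel)) < aged_fraction
    }
    cv <- error$count_cv
    for (k in 1:3) {
      cnt <- rep(NA_real_, nf)
      a <- which(fish$aged)
      cnt[a] <- pmax(1, round(fish$true_age_days[a] *
                                (1 + stats::rnorm(length(a), 0, cv))))
      fish[[paste0("count", k)]] <- as.integer(cnt)
    }
    fish$pre_settlement_count <- NA_integer_
    a <- which(fish$aged)
    core <- a[stats::runif(length(a)) < pld_read_fraction]
    fish$pre_settlement_count[core] <-
      as.integer(pmax(1, round(fish$true_pld_days[core])))
    rownames(fish) <- NULL
    cols <- c("fish_id", "collection_date", "total_length_mm",
              "fork_length_mm", "weight_g", "count1", "count2", "count3",
              "pre_settlement_count", "aged",
              "true_age_days", "true_pld_days", "true_hatch_date")
    fish <- fish[, cols]
    attr(fish, "dropped") <- dropped
    fish
  })
}

#' Generate a daily environmental series
#'
#' Daily night-time SST follows a sinusoid
#' `mean + amplitude * cos(2*pi*(day - peak_day)/365.25)` plus Gaussian
#' noise; rainfall is a zero-inflated gamma; flood gauge height relaxes
#' toward a base level with rainfall-driven excursions. The series covers
#' every date in the range with no gaps.
#'
#' @param date_range length-2 `Date` vector (closed).
#' @param sst_mean_C,sst_amplitude_C sinusoid mean and amplitude (deg C).
#' @param sst_peak_date date of the annual SST maximum (any year; only the
#'   day-of-year is used). Default Feb 1, austral late summer.
#' @param sst_noise_sd_C sd of daily SST noise.
#' @param rain_prob probability of a wet day.
#' @param rain_mean_mm mean rainfall on wet days (mm).
#' @param seed integer seed.
#' @return data.frame with columns `date`, `sst_C`, `rainfall_mm`,
#'   `flood_height_m`.
#' @export
generate_env_series <- function(date_range, sst_mean_C = 24,
                                sst_amplitude_C = 3.5,
                                sst_peak_date = as.Date("2020-02-01"),
                                sst_noise_sd_C = 0.3,
                                rain_prob = 0.25, rain_mean_mm = 8,
                                seed = 1) {
  date_range <- as_date(date_range)
  stopifnot(length(date_range) == 2L, date_range[1] <= date_range[2])
  dates <- seq(date_range[1], date_range[2], by = "day")
  doy_peak <- as.integer(format(as_date(sst_peak_date), "%j"))
  doy <- as.integer(format(dates, "%j"))
  with_seed(seed, {
    sst <- sst_mean_C + sst_amplitude_C *
      cos(2 * pi * (doy - doy_peak) / 365.25) +
      stats::rnorm(length(dates), 0, sst_noise_sd_C)
    wet <- stats::runif(length(dates)) < rain_prob
    rain <- ifelse(wet, stats::rgamma(length(dates), shape = 1,
                                      scale = rain_mean_mm), 0)
    flood <- stats::filter(rain / 40, 0.9, method = "recursive")
    flood <- 1.5 + as.numeric(flood)
    data.frame(date = dates, sst_C = sst, rainfall_mm = rain,
               flood_height_m = flood)
  })
}

#' Simulate a complete synthetic collection
#'
#' Convenience wrapper tying the generator together: builds a multi-year
#' spawning regime (two pulses per austral year in spring and late summer
#' plus a year-round background), samples hatch dates, realizes fish against
#' 2-3 trips per collection period, and generates the matching environmental
#' series.
#'
#' @param years integer vector of austral-year labels to cover.
#' @param n_fish total number of juveniles collected across all years.
#' @param seed integer seed.
#' @param count_cv,aged_fraction passed to the error model / realization.
#' @return list with elements `fish` (data.frame), `env` (data.frame),
#'   `regime`, `growth`, `error`, `trip_dates`.
#' @export
simulate_collection <- function(years, n_fish = 1763, seed = 1,
                                count_cv = 0.03, aged_fraction = 0.43) {
  years <- sort(as.integer(years))
  # two discrete pulses per austral year (spring, late summer), narrow
  # enough that the 30-day gap rule separates them as the study's visual
  # inspection did; no uniform background by default so cohorts stay
  # temporally discrete
  comps <- do.call(rbind, lapply(years, function(y) {
    data.frame(
      peak_date = as.Date(c(sprintf("%d-10-20", y), sprintf("%d-03-01", y + 1))),
      spread_days = c(14, 16),
      weight = c(1, 0.8))
  }))
  range <- c(austral_year_start(min(years)), austral_year_end(max(years)))
  regime <- spawning_regime(comps, background_rate = 0, date_range = range)
  growth <- growth_model()
  error <- ageing_error_model(count_cv = count_cv)
  # 2-3 trips per austral year, autumn/winter after the spawning season
  trips <- do.call(c, lapply(years, function(y) {
    as.Date(c(sprintf("%d-03-15", y + 1), sprintf("%d-06-05", y + 1),
              sprintf("%d-08-20", y + 1)))
  }))
  hatch <- sample_hatch_dates(regime, n_fish, seed = derive_seed(seed, 11))
  fish <- realize_fish(hatch, growth, error, trips,
                       seed = derive_seed(seed, 23),
                       aged_fraction = aged_fraction)
  env <- generate_env_series(c(range[1], max(trips)),
                             seed = derive_seed(seed, 37))
  list(fish = fish, env = env, regime = regime, growth = growth,
       error = error, trip_dates = trips)
}
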