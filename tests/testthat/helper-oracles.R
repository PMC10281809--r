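# Independent oracles and fixture builders used across the suite.

# New-moon instants from the classical lunation-polynomial method
# (mean new moon JDE plus periodic corrections). Entirely independent of
# the package's illumination-minimization route.
oracle_new_moons <- function(start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  ystart <- as.numeric(format(start_date, "%Y")) +
    as.numeric(format(start_date, "%j")) / 365.25
  k0 <- floor((ystart - 2000) * 12.3685) - 2
  out <- c()
  for (k in k0:(k0 + 30)) {
    T <- k / 1236.85
    jde <- 2451550.09766 + 29.530588861 * k +
      0.00015437 * T^2 - 0.000000150 * T^3 + 0.00000000073 * T^4
    E <- 1 - 0.002516 * T - 0.0000074 * T^2
    M <- (2.5534 + 29.10535670 * k - 0.0000014 * T^2) * pi / 180
    Mp <- (201.5643 + 385.81693528 * k + 0.0107582 * T^2 +
             0.00001238 * T^3) * pi / 180
    F <- (160.7108 + 390.67050284 * k - 0.0016118 * T^2) * pi / 180
    Om <- (124.7746 - 1.56375588 * k + 0.0020672 * T^2) * pi / 180
    corr <- -0.40720 * sin(Mp) + 0.17241 * E * sin(M) +
      0.01608 * sin(2 * Mp) + 0.01039 * sin(2 * F) +
      0.00739 * E * sin(Mp - M) - 0.00514 * E * sin(Mp + M) +
      0.00208 * E^2 * sin(2 * M) - 0.00111 * sin(Mp - 2 * F) -
      0.00057 * sin(Mp + 2 * F) + 0.00056 * E * sin(2 * Mp + M) -
      0.00042 * sin(3 * Mp) + 0.00042 * E * sin(M + 2 * F) +
      0.00038 * E * sin(M - 2 * F) - 0.00024 * E * sin(2 * Mp - M) -
      0.00017 * sin(Om)
    jde <- jde + corr
    # JD (UTC, TT offset negligible at day precision) -> local AEST date
    local <- as.Date(floor(jde - 2440587.5 + 10 / 24), origin = "1970-01-01")
    out <- c(out, local)
  }
  out <- sort(unique(as.Date(out, origin = "1970-01-01")))
  out[out >= start_date & out <= end_date]
}

# Brute-force restatement of the replicate-count acceptance rule, written
# directly from its definition.
oracle_qc <- function(counts, tol = 0.10) {
  med <- sort(counts)[2]
  all(abs(counts - med) / med <= tol)
}

# One synthetic austral year with a single Gaussian spawning pulse.
make_unimodal_year <- function(year = 2019, peak_doy = 150, spread = 15,
                               n = 300, seed = 1) {
  start <- as.Date(sprintf("%d-07-01", year))
  reg <- spawning_regime(
    data.frame(peak_date = start + peak_doy, spread_days = spread,
               weight = 1),
    background_rate = 0,
    date_range = c(start, as.Date(sprintf("%d-06-30", year + 1))))
  h <- sample_hatch_dates(reg, n, seed = seed)
  list(regime = reg, hatch = h, series = bin_hatch_dates(h, year),
       peak_date = start + peak_doy)
}

make_bimodal_year <- function(year = 2019, doy1 = 120, doy2 = 220,
                              spread = 12, n = 400, seed = 1) {
  start <- as.Date(sprintf("%d-07-01", year))
  reg <- spawning_regime(
    data.frame(peak_date = c(start + doy1, start + doy2),
               spread_days = spread, weight = c(1, 1)),
    background_rate = 0,
    date_range = c(start, as.Date(sprintf("%d-06-30", year + 1))))
  h <- sample_hatch_dates(reg, n, seed = seed)
  list(regime = reg, hatch = h, series = bin_hatch_dates(h, year),
       peak_dates = c(start + doy1, start + doy2))
}

# Aged-fish table from a known cubic age-length curve with per-cohort
# intercepts; used for recovery tests of the age-length model.
make_cubic_agelength <- function(n_per_cohort = 120,
                                 beta = c(-30, 1.8, -0.006, 3e-5),
                                 cohort_shift = c(-4, 0, 4),
                                 sigma_fun = function(L) 2 + 0.02 * L,
                                 seed = 1) {
  set.seed(seed)
  cohort_dates <- as.Date(c("2019-01-15", "2019-06-15", "2019-11-15"))
  rows <- list()
  for (ci in seq_along(cohort_shift)) {
    L <- runif(n_per_cohort, 30, 240)
    mu <- beta[1] + beta[2] * L + beta[3] * L^2 + beta[4] * L^3 +
      cohort_shift[ci]
    age <- mu + rnorm(n_per_cohort, 0, sigma_fun(L))
    rows[[ci]] <- data.frame(
      fish_id = sprintf("S%d_%03d", ci, seq_len(n_per_cohort)),
      total_length_mm = L,
      post_settlement_age_days = pmax(age, 1),
      hatch_date = cohort_dates[ci] + sample(-10:10, n_per_cohort, TRUE))
  }
  do.call(rbind, rows)
}
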