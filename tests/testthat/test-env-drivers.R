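test_that("illuminated fraction matches the phase definition at the cardinal
           phases", {
  # astronomical-almanac instants (UTC): new 2021-10-06 11:05,
  # first quarter 2021-10-13 03:25, full 2021-10-20 14:57
  f <- function(s) lunar_illumination(as.POSIXct(s, tz = "UTC"),
                                      shift_hours = 0)
  expect_lt(f("2021-10-06 11:05:00"), 0.01)
  expect_gt(f("2021-10-20 14:57:00"), 0.99)
  expect_equal(f("2021-10-13 03:25:00"), 0.5, tolerance = 0.04)
  # the +10 h shift moves the evaluation instant back 10 hours
  expect_equal(
    lunar_illumination(as.POSIXct("2021-10-06 21:05:00", tz = "UTC")),
    f("2021-10-06 11:05:00"), tolerance = 1e-12)
})

test_that("illumination is periodic at the synodic month", {
  t0 <- seq(as.POSIXct("2015-03-01", tz = "UTC"),
            by = "13 days", length.out = 30)
  v0 <- lunar_illumination(t0)
  v1 <- lunar_illumination(t0 + 29.530588 * 86400)
  # individual lunations genuinely run 29.27-29.83 d, so near the quarters
  # (max |d illum/dt|) one-cycle differences can reach ~0.03; the mean-cycle
  # periodicity shows as a small typical difference plus a tight bound at
  # the phase extremes
  expect_lt(median(abs(v1 - v0)), 0.02)
  expect_lt(max(abs(v1 - v0)), 0.05)
  extremes <- v0 < 0.05 | v0 > 0.95
  expect_gt(sum(extremes), 3)
  expect_lt(max(abs(v1 - v0)[extremes]), 0.02)
})

test_that("environmental bins align with spawning bins and reproduce a known
           SST field", {
  y <- make_unimodal_year(year = 2018, n = 100, seed = 2)
  env <- generate_env_series(as.Date(c("2018-06-20", "2019-07-10")),
                             sst_noise_sd_C = 0, seed = 3)
  eb <- build_env_bins(env, y$series)
  expect_equal(nrow(eb), 73)
  expect_equal(eb$start_date, y$series$bins$start_date)
  expect_equal(eb$spawn_count, y$series$bins$count)
  expect_true(all(eb$lunar_illumination >= 0 & eb$lunar_illumination <= 1))

  # constant SST passes through exactly
  env2 <- env
  env2$sst_C <- 25
  eb2 <- build_env_bins(env2, y$series)
  expect_true(all(abs(eb2$sst_C - 25) < 1e-9))

  # noise-free sinusoid: bin SSTs reproduce it within composite+interp error
  doy <- as.integer(format(eb$start_date + 2, "%j"))
  truth <- 24 + 3.5 * cos(2 * pi * (doy - 32) / 365.25)
  expect_lt(max(abs(eb$sst_C - truth)), 0.15)
})

test_that("SST gaps beyond the interpolation limit are flagged", {
  y <- make_unimodal_year(year = 2018, n = 50, seed = 4)
  env <- generate_env_series(as.Date(c("2018-06-20", "2019-07-10")), seed = 5)
  env$sst_C[env$date >= as.Date("2018-12-01") &
              env$date <= as.Date("2019-01-31")] <- NA
  eb <- suppressMessages(build_env_bins(env, y$series))
  expect_gt(sum(eb$flagged), 0)
  expect_true(all(!eb$flagged[eb$start_date < as.Date("2018-11-01")]))
})

test_that("an SST-driven signal selects the SST-month model and drops lunar
           terms", {
  # counts generated from SST alone over two years
  years <- 2018:2019
  env <- generate_env_series(as.Date(c("2018-06-20", "2020-07-10")),
                             sst_noise_sd_C = 0.1, seed = 6)
  series <- lapply(years, function(yy) {
    s <- bin_hatch_dates(as.Date(character()), yy)
    s
  })
  set.seed(7)
  ebs <- lapply(seq_along(years), function(i) {
    eb <- build_env_bins(env, series[[i]])
    mu <- exp(1.2 * (eb$sst_C - 24))          # monotone SST response
    eb$spawn_count <- rpois(nrow(eb), mu)
    eb
  })
  eb <- do.call(rbind, ebs)
  fit <- fit_env_smooth(eb, p_grid = c(1.2, 1.5, 1.8))
  expect_true(fit$model %in% c("sst_month"))
  # never selects beyond the AICc equivalence margin of the best candidate
  expect_equal(fit$selection$aicc, sort(fit$selection$aicc))
  expect_lte(fit$aicc, min(fit$selection$aicc) + fit$aicc_tie)
  # the fitted partial SST response is monotone where the truth is monotone
  grid <- data.frame(sst_C = seq(quantile(eb$sst_C, 0.1),
                                 quantile(eb$sst_C, 0.9), length.out = 30),
                     month = 1, year_f = factor(2018,
                                                levels = c(2018, 2019)),
                     lunar_illumination = 0.5, rainfall_mm = 0)
  pr <- mgcv::predict.gam(fit$gam, newdata = grid, type = "link",
                          exclude = "s(year_f)")
  expect_gt(cor(grid$sst_C, as.numeric(pr), method = "spearman"), 0.9)
})

test_that("a duplicated covariate is flagged by the concurvity check", {
  y1 <- make_unimodal_year(year = 2018, n = 200, seed = 8)
  y2 <- make_unimodal_year(year = 2019, n = 200, seed = 9)
  env <- generate_env_series(as.Date(c("2018-06-20", "2020-07-10")), seed = 10)
  eb <- rbind(build_env_bins(env, y1$series), build_env_bins(env, y2$series))
  eb$lunar_illumination <- eb$sst_C / 40  # alias of SST entered twice
  dat <- eb
  fit <- suppressWarnings(
    mgcv::gam(spawn_count ~ s(sst_C, k = 5) +
                s(lunar_illumination, k = 5),
              family = mgcv::Tweedie(p = 1.5, link = "log"),
              data = dat, method = "GCV.Cp"))
  conc <- mgcv::concurvity(fit, full = FALSE)$estimate
  off <- conc
  diag(off) <- 0
  expect_gt(max(off), 0.99)
})

test_that("with no covariate signal the null model usually wins AICc", {
  years <- 2018:2019
  env <- generate_env_series(as.Date(c("2018-06-20", "2020-07-10")),
                             seed = 20)
  series <- lapply(years, function(yy) bin_hatch_dates(as.Date(character()),
                                                       yy))
  wins <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    set.seed(100 + r)
    ebs <- lapply(seq_along(years), function(i) {
      eb <- build_env_bins(env, series[[i]])
      eb$spawn_count <- rpois(nrow(eb), 3)   # independent of everything
      eb
    })
    fit <- fit_env_smooth(do.call(rbind, ebs), p_grid = c(1.3, 1.6))
    if (fit$model == "null") wins <- wins + 1L
  }
  expect_gte(wins, 0.8 * n_rep)
})
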