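test_that("gap rule splits hatch dates into ordered cohort windows", {
  # two tight clusters 120 days apart
  d <- as.Date("2019-01-01") + c(0:10, 120:132)
  co <- define_cohorts(d, gap_days = 30)
  expect_equal(nrow(co), 2)
  expect_true(all(co$start_date <= co$end_date))
  expect_true(all(diff(as.numeric(co$start_date)) > 0))
  expect_equal(co$n, c(11L, 13L))

  expect_equal(nrow(define_cohorts(as.Date("2019-01-01"))), 1)
  expect_equal(define_cohorts(as.Date("2019-01-01"))$start_date,
               define_cohorts(as.Date("2019-01-01"))$end_date)

  # six well-separated generator pulses are recovered as six cohorts
  range <- as.Date(c("2018-07-01", "2021-06-30"))
  peaks <- as.Date(c("2018-10-15", "2019-02-20", "2019-10-15",
                     "2020-02-20", "2020-10-15", "2021-02-20"))
  reg <- spawning_regime(
    data.frame(peak_date = peaks, spread_days = 10, weight = 1), 0, range)
  h <- sample_hatch_dates(reg, 600, seed = 6)
  co6 <- define_cohorts(h, gap_days = 30)
  expect_equal(nrow(co6), 6)
  expect_true(all(abs(as.numeric(co6$midpoint - peaks)) < 10))
})

test_that("noise-free cubic data are recovered to 4 significant figures", {
  beta <- c(-30, 1.8, -0.006, 3e-5)
  dat <- make_cubic_agelength(n_per_cohort = 60, beta = beta,
                              cohort_shift = c(-5, 0, 5),
                              sigma_fun = function(L) 0, seed = 2)
  co <- define_cohorts(dat$hatch_date, gap_days = 30)
  fit <- suppressMessages(fit_age_length(dat, co))
  expect_equal(fit$engine, "lm-fallback") # interpolation limit, logged
  expect_equal(unname(fit$fixed_coefficients), beta, tolerance = 1e-4)
  # in-range prediction reproduces the generating curve
  L <- c(50, 120, 200)
  mu <- beta[1] + beta[2] * L + beta[3] * L^2 + beta[4] * L^3
  expect_equal(predict_age(fit, L, "marginal")$age_days, mu,
               tolerance = 1e-6)
})

test_that("dispersion model recovers a positive variance-length slope", {
  dat <- make_cubic_agelength(n_per_cohort = 150,
                              sigma_fun = function(L) 2 + 0.05 * L,
                              seed = 3)
  co <- define_cohorts(dat$hatch_date, gap_days = 30)
  fit <- fit_age_length(dat, co)
  expect_equal(fit$engine, "glmmTMB")
  # interval width must grow with length (positive dispersion slope)
  w <- function(L) {
    p <- predict_age(fit, L, "marginal")
    p$upr - p$lwr
  }
  expect_gt(w(220), w(60))
  expect_true(all(diff(vapply(c(60, 120, 180, 230), w, numeric(1))) > 0))
})

test_that("identical cohorts drive the cohort variance to zero", {
  dat <- make_cubic_agelength(n_per_cohort = 100,
                              cohort_shift = c(0, 0, 0), seed = 4)
  co <- define_cohorts(dat$hatch_date, gap_days = 30)
  fit <- suppressMessages(fit_age_length(dat, co))
  # either the mixed fit shrinks the cohort sd to ~0 or the singular-variance
  # fallback fires; both report a near-zero cohort sd
  expect_lt(fit$cohort_sd, 1.5)
})

test_that("cohort effects are centred and shift predictions additively", {
  dat <- make_cubic_agelength(n_per_cohort = 150,
                              cohort_shift = c(-5, 0, 5), seed = 5)
  co <- define_cohorts(dat$hatch_date, gap_days = 30)
  fit <- fit_age_length(dat, co)
  expect_lt(abs(mean(fit$cohort_effects)), 1)
  cid <- names(which.max(fit$cohort_effects))
  delta <- max(fit$cohort_effects)
  diff_pred <- predict_age(fit, 120, cid)$age_days -
    predict_age(fit, 120, "marginal")$age_days
  expect_equal(diff_pred, delta, tolerance = 1e-6)
})

test_that("collection dates map to cohorts with the documented tie-breaks", {
  d <- as.Date("2019-01-01") + c(0:10, 200:210)
  co <- define_cohorts(d, gap_days = 30)
  fit <- list(age_range = c(40, 100), mean_pld_days = 28, cohorts = co)
  class(fit) <- "age_length_fit"
  # inside exactly the first cohort's plausible interval
  expect_equal(assign_cohort(as.Date("2019-01-05") + 70, co, fit), "C01")
  # far outside every interval
  expect_equal(assign_cohort(as.Date("2021-06-01"), co, fit), "marginal")
  # overlapping intervals: equidistant date goes to the earlier cohort
  fit$age_range <- c(40, 260)
  lo <- as.numeric(co$start_date) + 40 + 28
  hi <- as.numeric(co$end_date) + 260 + 28
  mid <- (lo + hi) / 2
  eq <- as.Date(round(mean(mid)), origin = "1970-01-01")
  expect_equal(assign_cohort(eq, co, fit), "C01")
})

test_that("prediction refuses to extrapolate beyond the length range", {
  dat <- make_cubic_agelength(seed = 6)
  co <- define_cohorts(dat$hatch_date, gap_days = 30)
  fit <- fit_age_length(dat, co)
  expect_error(predict_age(fit, 500), "no extrapolation")
  expect_error(predict_age(fit, 1), "no extrapolation")
  expect_silent(predict_age(fit, fit$length_range[2] + 0.05 *
                              diff(fit$length_range)))
})

test_that("imputed ages of non-aged fish are approximately unbiased", {
  sim <- simulate_collection(2018:2019, n_fish = 1400, seed = 13)
  fish <- age_fish(sim$fish)
  fish <- back_calculate(fish, estimate_pld(fish)$mean_days)
  co <- define_cohorts(fish$hatch_date[fish$aged], gap_days = 30)
  fit <- fit_age_length(fish[fish$aged, ], co)
  fish <- impute_ages(fish, fit)
  imp <- fish[fish$imputed, ]
  expect_gt(nrow(imp), 500)
  err <- imp$post_settlement_age_days - imp$true_age_days
  expect_lt(abs(mean(err)), 2)
})
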