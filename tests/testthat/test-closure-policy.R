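test_that("new-moon dates agree with the lunation-polynomial oracle", {
  for (yr in c(2007, 2011, 2021)) {
    got <- new_moons(as.Date(sprintf("%d-10-01", yr)),
                     as.Date(sprintf("%d-12-31", yr)))
    want <- oracle_new_moons(sprintf("%d-10-01", yr),
                             sprintf("%d-12-31", yr))
    expect_equal(length(got), length(want))
    expect_true(all(abs(as.numeric(got - want)) <= 1))
  }
  # the spring-summer season of 2021, dates known to the day
  got <- new_moons(as.Date("2021-10-01"), as.Date("2021-12-31"))
  expect_true(all(abs(as.numeric(
    got - as.Date(c("2021-10-06", "2021-11-05", "2021-12-04")))) <= 1))
})

test_that("any 92-day window holds 3-4 new moons spaced a synodic month", {
  starts <- as.Date(c("2008-01-15", "2013-06-01", "2019-03-20"))
  for (s in seq_along(starts)) {
    m <- new_moons(starts[s], starts[s] + 91)
    expect_true(length(m) %in% c(3L, 4L))
  }
  m <- new_moons(as.Date("2010-01-01"), as.Date("2012-12-31"))
  gaps <- diff(as.numeric(m))
  expect_true(all(gaps >= 29 & gaps <= 31))   # whole-date rounding of 29.27-29.83
  expect_equal(mean(gaps), 29.53, tolerance = 0.01)
})

test_that("closure windows are centred, clipped and merged correctly", {
  season <- as.Date(c("2021-10-01", "2021-12-31"))
  m <- new_moons(season[1], season[2])

  w9 <- make_closures(m, 9, 3, season)
  expect_equal(sum(w9$duration_days), 27)
  expect_equal(w9$start_date, w9$anchor_new_moon - 4)
  expect_equal(w9$end_date, w9$anchor_new_moon + 4)

  w5 <- make_closures(m, 5, 2, season)
  expect_equal(sum(w5$duration_days), 10)
  # earliest moons first: October onward
  expect_equal(w5$anchor_new_moon, m[1:2])

  w1 <- make_closures(m, 1, 1, season)
  expect_equal(w1$start_date, w1$anchor_new_moon)
  expect_equal(w1$duration_days, 1)

  # windows wide enough to overlap are merged with a warning
  expect_warning(wb <- make_closures(m, 61, 3, season), "merged")
  expect_lt(nrow(wb), 3)
  expect_equal(sum(wb$duration_days),
               as.numeric(min(season[2], max(m) + 30) -
                            max(season[1], m[1] - 30)) + 1)
})

test_that("capture proportion is exact for uniform activity and invariant to
           scale", {
  season <- as.Date(c("2021-10-01", "2021-12-31"))
  m <- new_moons(season[1], season[2])
  w9 <- make_closures(m, 9, 3, season)
  w5 <- make_closures(m, 5, 2, season)

  uni <- function(days) rep(3.7, length(days))
  r9 <- capture_proportion(uni, w9, season)
  expect_equal(r9$captured_proportion, 27 / 92, tolerance = 1e-12)
  expect_equal(r9$expected_uniform, 27 / 92, tolerance = 1e-12)
  expect_equal(r9$closed_days, 27)
  r5 <- capture_proportion(uni, w5, season)
  expect_equal(r5$captured_proportion, 10 / 92, tolerance = 1e-12)

  # rescaling the activity curve changes nothing
  act <- data.frame(date = seq(season[1], season[2], by = "day"))
  set.seed(3)
  act$activity <- rgamma(nrow(act), 2, 0.5)
  p1 <- capture_proportion(act, w9, season)$captured_proportion
  act2 <- act
  act2$activity <- act2$activity * 137.5
  p2 <- capture_proportion(act2, w9, season)$captured_proportion
  expect_equal(p1, p2, tolerance = 1e-12)

  # activity confined to the windows is fully captured
  act3 <- act
  act3$activity <- 0
  inw <- Reduce(`|`, lapply(seq_len(nrow(w9)), function(i) {
    act3$date >= w9$start_date[i] & act3$date <= w9$end_date[i]
  }))
  act3$activity[inw] <- 1
  expect_equal(capture_proportion(act3, w9, season)$captured_proportion, 1)
  act3$activity <- 0
  expect_error(capture_proportion(act3, w9, season), "all-zero")
})

test_that("enlarging windows never decreases capture; merging never
           double-counts", {
  season <- as.Date(c("2021-10-01", "2021-12-31"))
  m <- new_moons(season[1], season[2])
  act <- data.frame(date = seq(season[1], season[2], by = "day"))
  set.seed(11)
  act$activity <- rgamma(nrow(act), 2, 0.5)
  caps <- vapply(c(1, 3, 5, 9, 15, 31), function(d) {
    w <- suppressWarnings(make_closures(m, d, 3, season))
    capture_proportion(act, w, season)$captured_proportion
  }, numeric(1))
  expect_true(all(diff(caps) >= -1e-12))

  # overlap handling: capture of merged windows equals capture of the union
  w_wide <- suppressWarnings(make_closures(m, 45, 3, season))
  union_days <- unique(do.call(c, lapply(seq_len(nrow(w_wide)), function(i) {
    seq(w_wide$start_date[i], w_wide$end_date[i], by = "day")
  })))
  manual <- sum(act$activity[act$date %in% union_days]) / sum(act$activity)
  expect_equal(capture_proportion(act, w_wide, season)$captured_proportion,
               manual, tolerance = 1e-12)
})

test_that("closure evaluation and the Beta capture model behave under a
           uniform-activity reference", {
  # uniform activity in every year: captures are closed_days/92 exactly,
  # so the fitted 9:5 duration ratio sits near 9/5 = 1.8
  season_years <- 2016:2021
  rows <- lapply(season_years, function(y) {
    season <- as.Date(sprintf("%d-%s", y, c("10-01", "12-31")))
    m <- new_moons(season[1], season[2])
    do.call(rbind, lapply(c(5, 9), function(d) {
      do.call(rbind, lapply(1:3, function(k) {
        w <- make_closures(m, d, k, season)
        capture_proportion(function(dd) rep(1, length(dd)), w, season)
      }))
    }))
  })
  res <- do.call(rbind, rows)
  fit <- fit_capture_model(res)
  expect_equal(fit$duration_ratio, 1.8, tolerance = 0.1)
  expect_equal(nrow(fit$count_contrasts), 3)

  # all-equal proportions: zero slopes after the boundary transform
  flat <- res
  flat$captured_proportion <- 0.2
  ffit <- fit_capture_model(flat)
  expect_lt(abs(log(ffit$duration_ratio)), 1e-4)
  expect_true(all(abs(ffit$count_contrasts$estimate) < 1e-4))
})

test_that("raw-count activity conserves totals and matches a manual tally", {
  h <- as.Date("2019-07-01") + sample.int(365, 200, replace = TRUE) - 1
  s <- bin_hatch_dates(h, 2019)
  act <- raw_daily_activity(s)
  expect_equal(nrow(act), 366)           # leap-spanning austral year
  expect_equal(sum(act$activity) / 5, s$n_total, tolerance = 1e-9)

  season <- as.Date(c("2019-10-01", "2019-12-31"))
  m <- new_moons(season[1], season[2])
  w <- make_closures(m, 9, 3, season)
  r <- capture_proportion(act, w, season)
  sdays <- seq(season[1], season[2], by = "day")
  closed <- Reduce(`|`, lapply(seq_len(nrow(w)), function(i) {
    sdays >= w$start_date[i] & sdays <= w$end_date[i]
  }))
  manual <- sum(act$activity[match(sdays[closed], act$date)]) /
    sum(act$activity[match(sdays, act$date)])
  expect_equal(r$captured_proportion, manual, tolerance = 1e-12)
})

test_that("a simulated null closure effect is called null most of the time", {
  # proportions independent of duration and count: coefficients should sit
  # within 2 se of zero in >= 90% of replicates
  season_years <- 2015:2021
  template <- expand.grid(year_label = season_years, duration_days = c(5, 9),
                          n_closures = 1:3)
  n_rep <- 50L
  zmat <- NULL
  for (r in seq_len(n_rep)) {
    set.seed(300 + r)
    res <- template
    res$captured_proportion <- plogis(rnorm(nrow(res), qlogis(0.15), 0.3))
    res$expected_uniform <- 0.15
    res$closed_days <- res$duration_days * res$n_closures
    fit <- fit_capture_model(res)
    sm <- summary(fit$fit)$coefficients$cond
    eff <- c("duration_f9", "count_f2", "count_f3")
    z <- abs(sm[eff, "Estimate"] / sm[eff, "Std. Error"])
    zmat <- rbind(zmat, z)
  }
  # each design coefficient sits within 2 se of zero in >= 90% of replicates
  expect_true(all(colMeans(zmat < 2) >= 0.9))
})
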