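test_that("hourly_series sums bins into 60-minute totals", {
  rec <- square_record(2, level = 1)
  h <- hourly_series(rec)
  expect_length(h, 48)
  expect_equal(sort(unique(h)), c(0, 12))
  # mixed toy day: first 12 hours of 1s, rest 0
  counts <- matrix(c(rep(1, 144), rep(0, 144)), nrow = 1)
  rec2 <- activity_record(counts, 5, tibble::tibble(
    day = 1, phase = "DD", lights_on_h = NA, lights_off_h = NA,
    stress = FALSE))
  expect_equal(hourly_series(rec2), c(rep(12, 12), rep(0, 12)))
  expect_equal(hourly_series(activity_record(matrix(0, 1, 288), 5,
    tibble::tibble(day = 1, phase = "DD", lights_on_h = NA,
                   lights_off_h = NA, stress = FALSE))), rep(0, 24))
})

test_that("interdaily stability is exactly 1 for identical nonconstant days", {
  expect_identical(interdaily_stability(hourly_series(square_record(9))), 1)
})

test_that("interdaily stability matches the literal formula and its bounds", {
  expect_equal(interdaily_stability(c(2, 0, 0, 0, 0, 0, 0, 2), p = 4), 1 / 3)
  set.seed(42)
  for (i in 1:20) {
    x <- rpois(24 * sample(2:5, 1), lambda = 5)
    if (var(x) == 0) next
    is_val <- interdaily_stability(x)
    expect_equal(is_val, is_literal(x), tolerance = 1e-12)
    expect_gte(is_val, 0)
    expect_lte(is_val, 1)
  }
  expect_error(interdaily_stability(rep(3, 48)), "zero-variance")
  expect_error(interdaily_stability(rnorm(30)), "multiple")
})

test_that("interdaily stability of long iid noise is near 1/n_days", {
  set.seed(7)
  expect_lt(interdaily_stability(rnorm(24 * 100)), 0.05)
})

test_that("intradaily variability: hand values, closed forms, limits", {
  expect_equal(intradaily_variability(c(0, 2, 0, 2)), 4)
  # hourly sinusoid: first-difference closed form 4*sin^2(pi/24) ~ 0.068
  x <- sin(2 * pi * (0:239) / 24)
  expect_equal(intradaily_variability(x), 0.0684, tolerance = 0.01)
  set.seed(11)
  expect_equal(intradaily_variability(rnorm(24 * 200)), 2, tolerance = 0.06)
  for (i in 1:20) {
    y <- rnorm(sample(3:10, 1))
    expect_equal(intradaily_variability(y), iv_literal(y), tolerance = 1e-12)
  }
  expect_error(intradaily_variability(rep(1, 10)), "zero-variance")
})

test_that("relative amplitude covers the boundary and arithmetic cases", {
  expect_equal(relative_amplitude(c(rep(10, 12), rep(0, 12)))$RA, 1)
  expect_equal(relative_amplitude(rep(5, 24))$RA, 0)
  ra <- relative_amplitude(c(rep(8, 12), rep(2, 12)))
  expect_equal(ra$M10, 8)
  expect_equal(ra$L5, 2)
  expect_equal(ra$RA, 0.6)
  # scaling invariance
  p <- c(rep(8, 10), rep(4, 9), rep(2, 5))
  expect_equal(relative_amplitude(p)$RA, relative_amplitude(3 * p)$RA)
  expect_error(relative_amplitude(rep(0, 24)), "all-zero")
})

test_that("activity profiles average days and anchor at ZT", {
  rec <- square_record(3, level = 6)
  prof <- activity_profile(rec)
  expect_equal(prof$mean_counts, hourly_series(square_record(1, level = 6)))
  # two days, all 2s and all 0s, average to 1s
  counts <- rbind(matrix(2, 1, 288), matrix(0, 1, 288))
  rec2 <- activity_record(counts, 5, tibble::tibble(
    day = 1:2, phase = "DD", lights_on_h = NA, lights_off_h = NA,
    stress = FALSE))
  # per-bin counts of 2 sum to 24/h on day 1, 0 on day 2: flat mean 12
  expect_equal(activity_profile(rec2)$mean_counts, rep(12, 24))
  # ZT anchoring puts the dark-phase activity at ZT12-ZT23
  zt <- activity_profile(rec, anchor = "ZT")
  expect_true(all(zt$mean_counts[13:24] > 0))
  expect_true(all(zt$mean_counts[1:12] == 0))
})

test_that("chi-square periodogram finds a 24-h square wave", {
  pg <- chi2_periodogram(square_record(6, level = 12))
  expect_equal(pg$best_period_h, 24)
  expect_true(glance(pg)$amplitude > 0)
})

test_that("periodogram recovers a noisy sinusoidal period near 23.5 h", {
  set.seed(3)
  t_h <- (0:1727) / 12
  x <- rpois(1728, lambda = 10 * (1 + sin(2 * pi * t_h / 23.5)))
  pg <- chi2_periodogram(x, bin_minutes = 5)
  expect_lte(abs(pg$best_period_h - 23.5), 1 / 12 + 1e-9)
})

test_that("periodogram rarely flags noise and rejects degenerate input", {
  set.seed(5)
  n_hit <- sum(vapply(1:20, function(i) {
    any(tidy(chi2_periodogram(10 + rnorm(1728), bin_minutes = 5))$significant)
  }, logical(1)))
  expect_lte(n_hit, 2)
  expect_error(chi2_periodogram(rep(4, 2000), bin_minutes = 5),
               "zero-variance")
  expect_error(chi2_periodogram(rnorm(100), bin_minutes = 5),
               "at least twice")
})

test_that("Qp is invariant under count scaling", {
  rec <- square_record(6)
  q1 <- tidy(chi2_periodogram(rec))$Qp
  rec2 <- rec
  rec2$counts <- rec$counts * 7
  expect_equal(tidy(chi2_periodogram(rec2))$Qp, q1, tolerance = 1e-12)
})

test_that("onsets are found at the start of the active phase", {
  ons <- detect_onsets(square_record(6))
  expect_equal(ons$onset_h, rep(18, 6))
  expect_equal(ons$day, 1:6)
  empty <- detect_onsets(activity_record(matrix(0, 3, 288), 5,
    tibble::tibble(day = 1:3, phase = "DD", lights_on_h = NA,
                   lights_off_h = NA, stress = FALSE)))
  expect_equal(nrow(empty), 0)
})

test_that("onset regression returns 24 + slope", {
  ons <- tibble::tibble(day = 1:6, onset_h = rep(18, 6))
  expect_equal(period_from_onsets(ons), 24)
  drift <- tibble::tibble(day = 1:9, onset_h = 18 + 0.5 * (0:8))
  expect_equal(period_from_onsets(drift), 24.5)
  set.seed(8)
  noisy <- tibble::tibble(day = 1:9, onset_h = 18 - 0.3 * (0:8) +
                            rnorm(9, 0, 0.2))
  expect_equal(period_from_onsets(noisy), 23.7, tolerance = 0.15)
  expect_error(period_from_onsets(drift[1:2, ]), "at least 3")
})

test_that("re-entrainment day counting follows the sustain rule", {
  pre <- tibble::tibble(day = 1:6, onset_h = rep(18, 6))
  # advances 1 h/day, holds at -7 from day 13 (7th post day)
  gradual <- dplyr::bind_rows(pre, tibble::tibble(
    day = 7:16, onset_h = c(17:11, 11, 11, 11)))
  r <- days_to_reentrain(gradual, advance_day = 7, advance_h = 7)
  expect_equal(r$days_to_reentrain, 7)
  expect_true(r$reentrained)
  expect_equal(r$onset_shift_h, 7)
  # jumps immediately and holds
  jump <- dplyr::bind_rows(pre, tibble::tibble(day = 7:10,
                                               onset_h = rep(11, 4)))
  expect_equal(days_to_reentrain(jump, 7, 7)$days_to_reentrain, 1)
  # touches tolerance on post day 5 but only holds from post day 8
  osc <- dplyr::bind_rows(pre, tibble::tibble(
    day = 7:16,
    onset_h = c(15, 14, 13, 12, 11.2, 13, 12.5, 11.1, 11, 11)))
  expect_equal(days_to_reentrain(osc, 7, 7,
                                 sustain_days = 2)$days_to_reentrain, 8)
  # never re-entrains
  stuck <- dplyr::bind_rows(pre, tibble::tibble(day = 7:12,
                                                onset_h = rep(17, 6)))
  r2 <- days_to_reentrain(stuck, 7, 7)
  expect_true(is.na(r2$days_to_reentrain))
  expect_false(r2$reentrained)
  expect_error(days_to_reentrain(pre, 7, 7), "span")
})

test_that("circadian_metrics bundles the measures coherently", {
  m <- circadian_metrics(square_record(6))
  expect_equal(m$IS, 1)
  expect_equal(m$RA, 1)
  expect_equal(m$period_periodogram_h, 24)
  expect_equal(m$period_onset_h, 24)
  expect_gt(m$amplitude, 0)
  rec0 <- activity_record(matrix(0, 3, 288), 5, tibble::tibble(
    day = 1:3, phase = "DD", lights_on_h = NA, lights_off_h = NA,
    stress = FALSE))
  expect_error(circadian_metrics(rec0), "all-zero")
})

test_that("simulated records recover the generating period", {
  rec <- simulate_activity(activity_sim_spec(
    tau_h = 23.7, fragmentation = 0.3, schedule = list(phase_dd(9)),
    seed = 21))
  m <- circadian_metrics(rec)
  expect_equal(m$period_periodogram_h, 23.7, tolerance = 0.1)
})
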