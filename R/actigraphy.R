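#' Hourly activity series
#'
#' Sums binned counts into consecutive 60-minute totals across the whole
#' record. The nonparametric rest-activity statistics ([interdaily_stability()],
#' [intradaily_variability()]) are defined on this hourly series.
#'
#' @param rec An [activity_record()].
#' @return Numeric vector of length `days * 24`.
#' @export
hourly_series <- function(rec) {
  stopifnot(inherits(rec, "activity_record"))
  x <- record_series(rec)
  per_h <- 60L %/% rec$bin_minutes
  as.vector(tapply(x, (seq_along(x) - 1) %/% per_h, sum))
}

#' Interdaily stability (IS)
#'
#' Day-to-day consistency of the activity rhythm: the variance of the mean
#' 24-h profile relative to the total variance of the hourly series,
#' `IS = (n * sum((xbar_h - xbar)^2)) / (p * sum((x_i - xbar)^2))` with `h`
#' running over the `p` fold positions (hours of day) and `i` over all `n`
#' hourly values. IS ranges from 0 (no daily structure) to 1 (every day
#' identical); for independent noise its expectation is about `p / n`, i.e.
#' `1 / n_days`.
#'
#' @param hourly Numeric series of hourly counts (or an [activity_record()],
#'   which is converted with [hourly_series()]).
#' @param p Fold length in samples (24 for hourly data).
#' @return A single number in \[0, 1\].
#' @export
interdaily_stability <- function(hourly, p = 24) {
  if (inherits(hourly, "activity_record")) hourly <- hourly_series(hourly)
  n <- length(hourly)
  if (n < p || n %% p != 0) {
    abort("series length must be a positive multiple of the fold length `p`")
  }
  xbar <- mean(hourly)
  ss_tot <- sum((hourly - xbar)^2)
  if (ss_tot == 0) abort("zero-variance series: IS undefined")
  hmeans <- colMeans(matrix(hourly, ncol = p, byrow = TRUE))
  n * sum((hmeans - xbar)^2) / (p * ss_tot)
}

#' Intradaily variability (IV)
#'
#' Fragmentation of the rhythm: the normalized mean square of successive
#' differences, `IV = n * sum(diff(x)^2) / ((n - 1) * sum((x - xbar)^2))`.
#' Smooth rhythms give values near 0; independent noise gives values near 2
#' (the expectation is `2n/(n-1)`); a strictly alternating series can exceed
#' 2 — the conventional 0–2 range describes typical data, not a bound.
#'
#' @inheritParams interdaily_stability
#' @return A single non-negative number.
#' @export
intradaily_variability <- function(hourly) {
  if (inherits(hourly, "activity_record")) hourly <- hourly_series(hourly)
  n <- length(hourly)
  if (n < 2) abort("need at least two values")
  ss_tot <- sum((hourly - mean(hourly))^2)
  if (ss_tot == 0) abort("zero-variance series: IV undefined")
  n * sum(diff(hourly)^2) / ((n - 1) * ss_tot)
}

#' Average daily activity profile
#'
#' Mean counts per hour of day across days, optionally anchored so the
#' profile starts at zeitgeber time 0 (lights-on; `anchor = "ZT"`) or at
#' circadian time 0 (12 h before the mean detected activity onset;
#' `anchor = "CT"`, for DD records).
#'
#' @param rec An [activity_record()].
#' @param anchor `"none"`, `"ZT"` or `"CT"`.
#' @param days Optional integer vector of days to include (default all).
#' @param ... Passed to [detect_onsets()] when `anchor = "CT"`.
#' @return Tibble with columns `hour` (0–23, in the anchored frame) and
#'   `mean_counts`.
#' @export
activity_profile <- function(rec, anchor = c("none", "ZT", "CT"),
                             days = NULL, ...) {
  stopifnot(inherits(rec, "activity_record"))
  anchor <- match.arg(anchor)
  sub <- rec
  if (!is.null(days)) {
    sub <- activity_record(rec$counts[days, , drop = FALSE], rec$bin_minutes,
                           rec$schedule[days, ], rec$start_clock_minutes)
  }
  hourly <- hourly_series(sub)
  prof <- colMeans(matrix(hourly, ncol = 24, byrow = TRUE))
  start_h <- sub$start_clock_minutes / 60
  shift <- 0
  if (anchor == "ZT") {
    on_h <- sub$schedule$lights_on_h[!is.na(sub$schedule$lights_on_h)]
    if (!length(on_h)) abort("anchor = 'ZT' needs at least one lighted day")
    shift <- (on_h[1] - start_h) %% 24
  } else if (anchor == "CT") {
    ons <- detect_onsets(sub, ...)
    if (nrow(ons) == 0) abort("anchor = 'CT' needs detectable onsets")
    # CT12 is activity onset for a nocturnal animal
    shift <- (mean(ons$onset_h %% 24) - 12 - start_h) %% 24
  }
  k <- round(shift) %% 24
  if (k > 0) prof <- c(prof[(k + 1):24], prof[1:k])
  tibble(hour = 0:23, mean_counts = prof)
}

#' Relative amplitude (RA) of the daily profile
#'
#' `M10` is the largest mean over 10 consecutive hours of the average 24-h
#' profile, `L5` the smallest mean over 5 consecutive hours (both circular),
#' and `RA = (M10 - L5) / (M10 + L5)`. RA lies in \[0, 1\] and is invariant
#' under scaling of the profile.
#'
#' @param profile Numeric vector of 24 non-negative hourly means, or the
#'   tibble returned by [activity_profile()].
#' @return One-row tibble with columns `RA`, `M10`, `L5`.
#' @export
relative_amplitude <- function(profile) {
  if (is.data.frame(profile)) profile <- profile$mean_counts
  if (length(profile) != 24 || any(profile < 0)) {
    abort("`profile` must be 24 non-negative hourly means")
  }
  if (all(profile == 0)) abort("all-zero profile: RA undefined")
  wrapped <- c(profile, profile)
  win_mean <- function(w) {
    vapply(1:24, function(s) mean(wrapped[s:(s + w - 1)]), numeric(1))
  }
  m10 <- max(win_mean(10))
  l5 <- min(win_mean(5))
  tibble(RA = (m10 - l5) / (m10 + l5), M10 = m10, L5 = l5)
}

#' Chi-square periodogram (Sokolove–Bushell)
#'
#' For each trial period of `P` bins the series is folded into `P` phase
#' classes and the between-class sum of squares is referred to the overall
#' variance: `Qp = sum_h n_h * (M_h - Mbar)^2 / (SS_tot / N)` with class
#' means `M_h`, class sizes `n_h`, grand mean `Mbar` and total sum of
#' squares `SS_tot` over all `N` bins. Under the no-rhythm null `Qp`
#' follows a chi-square distribution with `P - 1` degrees of freedom. By
#' default every bin is used (`truncate = FALSE`); the classical variant
#' truncates the series to an integer number of complete periods, which
#' discards up to one cycle of data and widens the peak on short records.
#' Because the scan tests many periods, the significance line is
#' Bonferroni-corrected across trial periods by default, so a pure-noise
#' series rarely shows any significant period. The best period is the
#' `Qp` argmax among significant periods. `Qp` is invariant under scaling
#' of the counts.
#'
#' @param rec An [activity_record()] or numeric series of bin counts.
#' @param p_min_h,p_max_h Period search range in hours (default 20–28, the
#'   murine free-running range).
#' @param alpha Significance level for the chi-square threshold.
#' @param bin_minutes Bin width; taken from `rec` when it is a record.
#' @param truncate Use the classical truncated folding instead of all bins.
#' @param adjust Multiplicity correction for the significance line across
#'   trial periods: `"bonferroni"` (default) or `"none"`.
#' @return An object of class `periodogram_result`; use [tidy()] for the
#'   per-period table and [glance()] for the best period and peak amplitude.
#' @export
chi2_periodogram <- function(rec, p_min_h = 20, p_max_h = 28, alpha = 0.05,
                             bin_minutes = NULL, truncate = FALSE,
                             adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (inherits(rec, "activity_record")) {
    bin_minutes <- rec$bin_minutes
    x <- record_series(rec)
  } else {
    x <- as.numeric(rec)
    if (is.null(bin_minutes)) abort("`bin_minutes` required for a bare series")
  }
  bin_h <- bin_minutes / 60
  n <- length(x)
  if (n * bin_h < 2 * p_max_h) {
    abort("record must span at least twice the maximum trial period")
  }
  if (var(x) == 0) abort("no rhythm detectable: zero-variance series")
  p_bins <- seq.int(ceiling(p_min_h / bin_h), floor(p_max_h / bin_h))
  res <- vapply(p_bins, function(P) {
    if (truncate) {
      K <- n %/% P
      xs <- x[seq_len(K * P)]
      mbar <- mean(xs)
      mh <- colMeans(matrix(xs, nrow = K, byrow = TRUE))
      K * (K * P) * sum((mh - mbar)^2) / sum((xs - mbar)^2)
    } else {
      cls <- (seq_len(n) - 1L) %% P
      nh <- tabulate(cls + 1L, P)
      mh <- as.vector(rowsum(x, cls)) / nh
      mbar <- mean(x)
      sum(nh * (mh - mbar)^2) / (sum((x - mbar)^2) / n)
    }
  }, numeric(1))
  a_eff <- if (adjust == "bonferroni") alpha / length(p_bins) else alpha
  thr <- qchisq(1 - a_eff, df = p_bins - 1)
  tab <- tibble(
    period_h = p_bins * bin_h,
    Qp = res,
    df = p_bins - 1L,
    sig_threshold = thr,
    significant = res > thr
  )
  best <- if (any(tab$significant)) {
    cand <- tab[tab$significant, ]
    cand$period_h[which.max(cand$Qp)]
  } else {
    NA_real_
  }
  structure(list(table = tab, best_period_h = best, alpha = alpha,
                 bin_minutes = bin_minutes),
            class = "periodogram_result")
}

#' @export
print.periodogram_result <- function(x, ...) {
  cat(sprintf("<periodogram_result> %d trial periods (%.2f-%.2f h), alpha = %g\n",
              nrow(x$table), min(x$table$period_h), max(x$table$period_h),
              x$alpha))
  if (is.na(x$best_period_h)) {
    cat("no significant period\n")
  } else {
    cat(sprintf("best period: %.4f h\n", x$best_period_h))
  }
  invisible(x)
}

#' @rdname chi2_periodogram
#' @param x A `periodogram_result`.
#' @param ... Unused.
#' @export
tidy.periodogram_result <- function(x, ...) x$table

#' @rdname chi2_periodogram
#' @export
glance.periodogram_result <- function(x, ...) {
  amp <- NA_real_
  if (!is.na(x$best_period_h)) {
    row <- x$table[x$table$period_h == x$best_period_h, ]
    amp <- row$Qp - row$sig_threshold
  }
  tibble(best_period_h = x$best_period_h, amplitude = amp, alpha = x$alpha)
}

#' Detect daily activity onsets
#'
#' An onset is the start of the first bin opening a window of `active_h`
#' hours in which at least `frac_active` of bins are at or above the
#' activity threshold, preceded by `quiet_h` hours with fewer than
#' `1 - frac_active` active bins. The default threshold is half the median
#' of the record's nonzero bin counts: anchoring at the median itself
#' classifies only ~half of genuinely active bins as active under Poisson
#' count noise, while half the median separates active bouts from rest
#' cleanly. Before the window test, rest gaps up to `max_gap_h` hours that
#' are flanked by activity are closed (treated as active): fragmented
#' records intersperse short rest bouts through the active phase, which
#' otherwise delay and jitter the detected onset; closing interior gaps
#' does not move the onset of a clean record because it never extends an
#' active run outward. Successive onsets at least `min_separation_h` apart are chained
#' into a series; the day index advances by the rounded cycle count so
#' drifting (free-running) onsets unwrap correctly and missing days are
#' allowed.
#'
#' @param rec An [activity_record()].
#' @param quiet_h Required quiet span before the onset, hours.
#' @param active_h Span that must be active from the onset, hours.
#' @param frac_active Fraction of active bins required in the active span.
#' @param threshold Bin-count threshold; default half the median of
#'   nonzero bins.
#' @param min_separation_h Minimum spacing between successive onsets.
#' @param max_gap_h Longest interior rest gap (hours) closed before the
#'   window test.
#' @return Tibble with columns `day` (1-based), `onset_h` (clock hours,
#'   unwrapped: `onset_abs_h - 24 * (day - 1)`) and `onset_abs_h` (hours
#'   since record start). Empty when no onset qualifies.
#' @export
detect_onsets <- function(rec, quiet_h = 4, active_h = 1, frac_active = 0.75,
                          threshold = NULL, min_separation_h = 16,
                          max_gap_h = 0.5) {
  stopifnot(inherits(rec, "activity_record"))
  x <- record_series(rec)
  if (all(x == 0)) {
    return(tibble(day = integer(), onset_h = numeric(),
                  onset_abs_h = numeric()))
  }
  thr <- threshold %||% (median(x[x > 0]) / 2)
  act <- as.numeric(x >= thr)
  gap_bins <- floor(max_gap_h * 60 / rec$bin_minutes)
  if (gap_bins >= 1) {
    r <- rle(act)
    ends <- cumsum(r$lengths)
    for (j in seq_along(r$values)) {
      if (r$values[j] == 0 && r$lengths[j] <= gap_bins &&
          j > 1 && j < length(r$values)) {
        act[(ends[j] - r$lengths[j] + 1):ends[j]] <- 1
      }
    }
  }
  bin_h <- rec$bin_minutes / 60
  qb <- max(1L, round(quiet_h / bin_h))
  ab <- max(1L, round(active_h / bin_h))
  n <- length(x)
  ca <- c(0, cumsum(act))
  win_frac <- function(i, w) (ca[i + w] - ca[i]) / w # bins i .. i+w-1
  cand <- integer(0)
  for (i in seq.int(qb + 1L, n - ab + 1L)) {
    if (act[i] == 1 && win_frac(i, ab) >= frac_active &&
        win_frac(i - qb, qb) < (1 - frac_active)) {
      cand <- c(cand, i)
    }
  }
  if (!length(cand)) {
    return(tibble(day = integer(), onset_h = numeric(),
                  onset_abs_h = numeric()))
  }
  t_cand <- (cand - 1) * bin_h
  picked <- t_cand[1]
  last <- t_cand[1]
  for (t in t_cand[-1]) {
    if (t - last >= min_separation_h) {
      picked <- c(picked, t)
      last <- t
    }
  }
  day <- integer(length(picked))
  day[1] <- as.integer(floor(picked[1] / 24)) + 1L
  if (length(picked) > 1) {
    for (k in 2:length(picked)) {
      day[k] <- day[k - 1] + max(1L, as.integer(round(
        (picked[k] - picked[k - 1]) / 24)))
    }
  }
  tibble(day = day, onset_h = picked - 24 * (day - 1), onset_abs_h = picked)
}

#' Free-running period from onset regression
#'
#' The slope of the least-squares regression of unwrapped onset clock time
#' on day index, plus 24 h: a stable onset gives 24.0; an onset drifting
#' +0.5 h/day gives 24.5.
#'
#' @param onsets Tibble from [detect_onsets()] (columns `day`, `onset_h`).
#' @return Period in hours.
#' @export
period_from_onsets <- function(onsets) {
  if (nrow(onsets) < 3) abort("need at least 3 onsets for period regression")
  fit <- lm(onset_h ~ day, data = onsets)
  24 + unname(coef(fit)[2])
}

#' Days to re-entrain after a phase advance
#'
#' Counts the post-advance days until the activity onset is within `tol_h`
#' of the target (the pre-advance onset level minus `advance_h`) and stays
#' within tolerance for `sustain_days` consecutive observed days. Also
#' reports the achieved onset shift: the pre-advance onset level minus the
#' mean onset from the re-entrainment day onward. The pre-advance level is
#' the median of pre-advance onsets by default — robust to the occasional
#' late-detected onset on fragmented records — with the mean available.
#'
#' @param onsets Onset series from [detect_onsets()].
#' @param advance_day First day index under the advanced schedule.
#' @param advance_h Magnitude of the schedule advance, hours.
#' @param tol_h Tolerance around the target onset.
#' @param sustain_days Consecutive in-tolerance days required.
#' @param pre_center `"median"` (default) or `"mean"` pre-advance level.
#' @return One-row tibble: `days_to_reentrain` (NA when never met),
#'   `reentrained`, `target_onset_h`, `onset_shift_h`, `n_post_days`.
#' @export
days_to_reentrain <- function(onsets, advance_day, advance_h = 7,
                              tol_h = 0.5, sustain_days = 2,
                              pre_center = c("median", "mean")) {
  pre_center <- match.arg(pre_center)
  if (advance_h <= 0) abort("`advance_h` must be positive")
  pre <- onsets[onsets$day < advance_day, ]
  post <- onsets[onsets$day >= advance_day, ]
  if (nrow(pre) == 0 || nrow(post) == 0) {
    abort("onset series must span pre- and post-advance days")
  }
  level <- if (pre_center == "median") median(pre$onset_h) else
    mean(pre$onset_h)
  target <- level - advance_h
  within <- abs(post$onset_h - target) <= tol_h
  hit <- NA_integer_
  for (k in seq_len(nrow(post))) {
    span <- which(post$day >= post$day[k] &
                    post$day <= post$day[k] + sustain_days - 1)
    if (length(span) >= sustain_days && all(within[span]) && within[k]) {
      hit <- k
      break
    }
  }
  if (is.na(hit)) {
    return(tibble(days_to_reentrain = NA_integer_, reentrained = FALSE,
                  target_onset_h = target, onset_shift_h = NA_real_,
                  n_post_days = nrow(post)))
  }
  settled <- post[post$day >= post$day[hit], ]
  tibble(
    days_to_reentrain = post$day[hit] - advance_day + 1L,
    reentrained = TRUE,
    target_onset_h = target,
    onset_shift_h = level - mean(settled$onset_h),
    n_post_days = nrow(post)
  )
}

#' Bundle of circadian metrics for one record
#'
#' Computes both period estimators (periodogram and onset regression), the
#' nonparametric statistics IS, IV and RA with M10/L5, and the periodogram
#' amplitude (peak `Qp` excess over the significance threshold) for a set
#' of days of one record.
#'
#' @param rec An [activity_record()].
#' @param days Optional day subset.
#' @param anchor Profile anchor for RA (see [activity_profile()]).
#' @param alpha Periodogram significance level.
#' @param p_min_h,p_max_h Periodogram search range.
#' @param ... Passed to [detect_onsets()].
#' @return One-row tibble with columns `period_periodogram_h`,
#'   `period_onset_h`, `IS`, `IV`, `RA`, `M10`, `L5`, `amplitude`.
#' @export
circadian_metrics <- function(rec, days = NULL, anchor = "none",
                              alpha = 0.05, p_min_h = 20, p_max_h = 28, ...) {
  stopifnot(inherits(rec, "activity_record"))
  sub <- rec
  if (!is.null(days)) {
    sub <- activity_record(rec$counts[days, , drop = FALSE], rec$bin_minutes,
                           rec$schedule[days, ], rec$start_clock_minutes)
  }
  if (all(sub$counts == 0)) abort("all-zero record: metrics undefined")
  hourly <- hourly_series(sub)
  pg <- chi2_periodogram(sub, p_min_h = p_min_h, p_max_h = p_max_h,
                         alpha = alpha)
  g <- glance(pg)
  ons <- detect_onsets(sub, ...)
  per_onset <- if (nrow(ons) >= 3) period_from_onsets(ons) else NA_real_
  ra <- relative_amplitude(activity_profile(sub, anchor = anchor))
  tibble(
    period_periodogram_h = g$best_period_h,
    period_onset_h = per_onset,
    IS = interdaily_stability(hourly),
    IV = intradaily_variability(hourly),
    RA = ra$RA, M10 = ra$M10, L5 = ra$L5,
    amplitude = g$amplitude
  )
}
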