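#' Schedule phase builders
#'
#' A simulated wheel-running protocol is an ordered list of phase blocks:
#' light/dark (LD) days, a phase advance of the light schedule with gradual
#' re-entrainment, and constant-darkness (DD) days optionally carrying an
#' acute stress event that perturbs the free-running period from that day
#' on. The default protocol mirrors a common aging-study design: 9 LD days,
#' a 7-h phase advance with 9 days to re-entrain, 9 DD baseline days, and 9
#' post-stress DD days.
#'
#' @param n_days Number of days in the block.
#' @param lights_on_h,lights_off_h Clock hours of lights-on / lights-off.
#' @param advance_h Magnitude of the phase advance in hours (schedule moves
#'   earlier by this much at the start of the block).
#' @param reentrain_rate_h_per_day Hours per day by which the activity onset
#'   moves toward the advanced schedule.
#' @param stress_day Day within the block (1-based) on which the stress event
#'   occurs, or `NA` for none.
#' @param delta_tau_h Change in free-running period (hours) applied from the
#'   day after the stress event.
#' @return A phase-block list used in [activity_sim_spec()]'s `schedule`.
#' @name schedule_phases
NULL

#' @rdname schedule_phases
#' @export
phase_ld <- function(n_days, lights_on_h = 6, lights_off_h = 18) {
  stopifnot(n_days >= 1)
  if (lights_on_h < 0 || lights_on_h >= 24 || lights_off_h < 0 ||
      lights_off_h >= 24 || lights_on_h == lights_off_h) {
    abort("lights-on/off hours must be distinct clock hours in [0, 24)")
  }
  list(type = "LD", n_days = as.integer(n_days),
       lights_on_h = lights_on_h, lights_off_h = lights_off_h)
}

#' @rdname schedule_phases
#' @export
phase_advance <- function(n_days, advance_h = 7, reentrain_rate_h_per_day = 1) {
  stopifnot(n_days >= 1)
  if (advance_h <= 0 || advance_h >= 24) {
    abort("`advance_h` must be in (0, 24)")
  }
  if (reentrain_rate_h_per_day <= 0) {
    abort("`reentrain_rate_h_per_day` must be positive")
  }
  list(type = "advance", n_days = as.integer(n_days), advance_h = advance_h,
       reentrain_rate_h_per_day = reentrain_rate_h_per_day)
}

#' @rdname schedule_phases
#' @export
phase_dd <- function(n_days, stress_day = NA, delta_tau_h = 0) {
  stopifnot(n_days >= 1)
  if (!is.na(stress_day) && (stress_day < 1 || stress_day > n_days)) {
    abort("`stress_day` must lie within the block")
  }
  list(type = "DD", n_days = as.integer(n_days),
       stress_day = as.integer(stress_day), delta_tau_h = delta_tau_h)
}

#' Default wheel-running protocol
#' @rdname schedule_phases
#' @export
default_schedule <- function() {
  list(
    phase_ld(9),
    phase_advance(9, advance_h = 7, reentrain_rate_h_per_day = 1),
    phase_dd(9),
    phase_dd(9, stress_day = 1, delta_tau_h = -0.3)
  )
}

#' Specification for a simulated wheel-running record
#'
#' Parameters of the activity generator. Activity follows a two-state model:
#' each circadian cycle has an active window covering `active_frac` of the
#' cycle; within the active window a two-state (bout/rest) Markov chain with
#' per-bin flip probability `fragmentation` modulates the rate, giving
#' direct control over intradaily variability downstream. Counts per bin are
#' Poisson with the state's rate. Light masks activity: during LD/advance
#' days, bins in the light get `rate_rest` regardless of circadian state.
#' In DD the onset drifts by `tau_h - 24` hours per day; after a stress day
#' the period changes by the block's `delta_tau_h`.
#'
#' @param tau_h Free-running period in hours, in \[20, 28\].
#' @param bin_minutes Bin width in minutes (default 5, must divide 60).
#' @param active_frac Fraction of the cycle spent in the active window.
#' @param rate_active,rate_rest Expected counts per bin in active bouts and
#'   in rest.
#' @param fragmentation Per-bin probability of a bout-state flip within the
#'   active window, in \[0, 1\].
#' @param schedule Ordered list of phase blocks (see [phase_ld()]).
#' @param seed Integer seed; identical specs with identical seeds give
#'   byte-identical records.
#' @return A list of class `activity_sim_spec`.
#' @export
activity_sim_spec <- function(tau_h = 23.8, bin_minutes = 5,
                              active_frac = 0.5, rate_active = 15,
                              rate_rest = 0.2, fragmentation = 0,
                              schedule = default_schedule(), seed = 1L) {
  assert_scalar_number(tau_h, "tau_h", 20, 28)
  assert_scalar_number(active_frac, "active_frac", 0, 1)
  assert_scalar_number(rate_active, "rate_active", 0)
  assert_scalar_number(rate_rest, "rate_rest", 0)
  assert_scalar_number(fragmentation, "fragmentation", 0, 1)
  assert_scalar_number(bin_minutes, "bin_minutes", 1, 60)
  if (60 %% bin_minutes != 0) abort("`bin_minutes` must divide 60")
  if (!length(schedule)) abort("`schedule` must contain at least one block")
  types <- vapply(schedule, function(b) b$type, character(1))
  if (!all(types %in% c("LD", "advance", "DD"))) {
    abort("unknown schedule block type")
  }
  if (types[1] == "advance") {
    abort("an advance block must follow an LD block")
  }
  structure(
    list(tau_h = tau_h, bin_minutes = bin_minutes, active_frac = active_frac,
         rate_active = rate_active, rate_rest = rate_rest,
         fragmentation = fragmentation, schedule = schedule,
         seed = as.integer(seed)),
    class = "activity_sim_spec"
  )
}

# expand phase blocks into a per-day schedule tibble, carrying light hours
# through advance blocks (shifted earlier by advance_h)
expand_schedule <- function(blocks) {
  rows <- list()
  day <- 0L
  on_h <- NA_real_; off_h <- NA_real_
  for (b in blocks) {
    if (b$type == "LD") {
      on_h <- b$lights_on_h; off_h <- b$lights_off_h
      for (i in seq_len(b$n_days)) {
        day <- day + 1L
        rows[[day]] <- tibble(day = day, phase = "LD", lights_on_h = on_h,
                              lights_off_h = off_h, stress = FALSE,
                              advance_h = 0, reentrain_rate = NA_real_,
                              delta_tau_h = 0)
      }
    } else if (b$type == "advance") {
      if (is.na(on_h)) abort("an advance block must follow an LD block")
      on_h <- (on_h - b$advance_h) %% 24
      off_h <- (off_h - b$advance_h) %% 24
      for (i in seq_len(b$n_days)) {
        day <- day + 1L
        rows[[day]] <- tibble(day = day, phase = "advance",
                              lights_on_h = on_h, lights_off_h = off_h,
                              stress = FALSE, advance_h = b$advance_h,
                              reentrain_rate = b$reentrain_rate_h_per_day,
                              delta_tau_h = 0)
      }
    } else {
      for (i in seq_len(b$n_days)) {
        day <- day + 1L
        rows[[day]] <- tibble(day = day, phase = "DD",
                              lights_on_h = NA_real_, lights_off_h = NA_real_,
                              stress = !is.na(b$stress_day) && i == b$stress_day,
                              advance_h = 0, reentrain_rate = NA_real_,
                              delta_tau_h = b$delta_tau_h)
      }
    }
  }
  bind_rows(rows)
}

# deterministic skeleton: per-day period and activity-onset clock hour
onset_skeleton <- function(spec, sched) {
  n <- nrow(sched)
  tau <- rep(spec$tau_h, n)
  stress_at <- which(sched$stress)
  if (length(stress_at)) {
    delta <- sched$delta_tau_h[stress_at[1]]
    if (stress_at[1] < n) {
      tau[(stress_at[1] + 1):n] <- spec$tau_h + delta
    }
  }
  onset <- numeric(n)
  for (d in seq_len(n)) {
    ph <- sched$phase[d]
    if (ph == "LD") {
      onset[d] <- sched$lights_off_h[d]
    } else if (ph == "advance") {
      target <- sched$lights_off_h[d]
      prev <- if (d == 1) target else onset[d - 1]
      # re-entrain toward the advanced dark onset, never overshooting
      step <- sched$reentrain_rate[d]
      cand <- prev - step
      onset[d] <- if (cand <= target) target else cand
    } else {
      prev <- if (d == 1) 18 else onset[d - 1]
      onset[d] <- prev + (tau[d] - 24)
    }
  }
  tibble(day = seq_len(n), tau_h = tau, onset_clock_h = onset,
         onset_abs_h = (seq_len(n) - 1) * 24 + onset)
}

#' Simulate a wheel-running activity record
#'
#' Generates a binned activity record under the protocol in
#' `spec$schedule`. The generator is deterministic given the seed and
#' records its own ground truth (per-day period and onset) in the
#' `truth` attribute for parameter-recovery tests.
#'
#' @param spec An [activity_sim_spec()].
#' @return An [activity_record()] with attribute `truth`, a tibble of per-day
#'   true period and onset.
#' @examples
#' rec <- simulate_activity(activity_sim_spec(
#'   tau_h = 24, schedule = list(phase_ld(6)), seed = 1
#' ))
#' dim(rec)
#' @export
simulate_activity <- function(spec) {
  stopifnot(inherits(spec, "activity_sim_spec"))
  sched <- expand_schedule(spec$schedule)
  skel <- onset_skeleton(spec, sched)
  n_days <- nrow(sched)
  bpd <- 1440L %/% as.integer(spec$bin_minutes)
  n_bins <- n_days * bpd
  bin_h <- spec$bin_minutes / 60
  t_start <- (seq_len(n_bins) - 1) * bin_h

  # circadian active windows from successive onsets
  starts <- skel$onset_abs_h
  cyc_len <- c(diff(starts), skel$tau_h[n_days])
  idx <- findInterval(t_start, starts)
  active <- idx >= 1L
  ok <- which(active)
  active[ok] <- (t_start[ok] - starts[idx[ok]]) <
    spec$active_frac * cyc_len[idx[ok]]

  # light masking on LD/advance days
  day_of <- pmin(floor(t_start / 24) + 1, n_days)
  clock <- t_start %% 24
  lighted <- sched$phase[day_of] != "DD"
  on_h <- sched$lights_on_h[day_of]
  off_h <- sched$lights_off_h[day_of]
  dark <- rep(TRUE, n_bins)
  li <- which(lighted)
  dark[li] <- ifelse(
    off_h[li] < on_h[li],
    clock[li] >= off_h[li] & clock[li] < on_h[li],
    clock[li] >= off_h[li] | clock[li] < on_h[li]
  )

  # fragmentation: two-state Markov chain restarted at each active window
  counts <- with_seed(spec$seed, {
    bout <- active
    if (spec$fragmentation > 0 && any(active)) {
      flips <- runif(n_bins) < spec$fragmentation
      r <- rle(active)
      ends <- cumsum(r$lengths)
      begins <- ends - r$lengths + 1L
      for (j in seq_along(r$values)) {
        if (!r$values[j]) next
        span <- begins[j]:ends[j]
        f <- flips[span]
        f[1] <- FALSE # windows start in the bout state
        bout[span] <- (cumsum(f) %% 2) == 0
      }
    }
    rate <- ifelse(active & bout, spec$rate_active, spec$rate_rest)
    rate[lighted & !dark] <- spec$rate_rest
    rpois(n_bins, rate)
  })

  rec <- activity_record(
    matrix(counts, nrow = n_days, ncol = bpd, byrow = TRUE),
    bin_minutes = spec$bin_minutes,
    schedule = sched[, c("day", "phase", "lights_on_h", "lights_off_h",
                         "stress")]
  )
  attr(rec, "truth") <- skel
  attr(rec, "spec") <- spec
  rec
}
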