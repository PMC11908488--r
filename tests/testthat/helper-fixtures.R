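# shared fixtures, all generated in code

# a smooth physiological-looking pupil signal (slow sine + gentle trend)
smooth_pupil <- function(n, rate = 60, amp = 50, base = 800) {
  t <- (seq_len(n) - 1) / rate
  base + amp * sin(2 * pi * 0.25 * t) + 2 * t
}

# trace with validity gaps at given (start, len) sample runs
gapped_trace <- function(values, gaps, rate = 60) {
  valid <- rep(TRUE, length(values))
  for (g in gaps) valid[seq(g[1], length.out = g[2])] <- FALSE
  pupil_trace(values, valid = valid, rate = rate)
}

# random recording for round-trip tests
random_recording <- function(n = 1000, rate = 60, seed = 1) {
  withr::with_seed(seed, {
    tm <- (seq_len(n) - 1) / rate * 1000
    df <- tibble::tibble(
      time_ms = tm,
      pupil_left = rnorm(n, 900, 40),
      pupil_right = rnorm(n, 880, 40),
      valid_left = runif(n) > 0.05,
      valid_right = runif(n) > 0.05,
      airflow = sin(2 * pi * tm / 4000) + rnorm(n, 0, 0.05))
    df$pupil_left[!df$valid_left] <- NA
    recording(df, participant_id = "p77", session_id = "s03",
              route = "mouth", unit = "px", rate = rate)
  })
}

# exhaustive sign-flip oracle: enumerate all 2^(sum n_b) sign assignments
# independently per bin (the max statistic couples bins, so enumerate the
# cartesian product of per-bin assignments)
exhaustive_max_t <- function(observations) {
  per_bin_t <- lapply(observations, function(x) {
    n <- length(x)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    apply(signs, 1, function(s) {
      y <- s * x
      mean(y) / (sd(y) / sqrt(n))
    })
  })
  grids <- expand.grid(lapply(per_bin_t, seq_along))
  max_t <- apply(grids, 1, function(ix)
    max(abs(mapply(function(tv, i) tv[i], per_bin_t, ix))))
  t_obs <- vapply(observations, function(x)
    mean(x) / (sd(x) / sqrt(length(x))), numeric(1))
  p <- vapply(abs(t_obs), function(t0) mean(max_t >= t0), numeric(1))
  list(t_obs = t_obs, p = p)
}

# analytic landmark table for perfectly regular breathing
regular_landmarks <- function(n_cycles = 4, inhale_ms = 2000,
                              exhale_ms = 2000) {
  cyc <- inhale_ms + exhale_ms
  onset <- (seq_len(n_cycles) - 1) * cyc
  lm <- tibble::tibble(
    cycle_id = seq_len(n_cycles),
    inhalation_onset = onset,
    inhalation_peak = onset + inhale_ms / 2,
    exhalation_onset = onset + inhale_ms,
    exhalation_peak = onset + inhale_ms + exhale_ms / 2,
    next_onset = onset + cyc)
  validate_cycles(lm)
}
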