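#' Configuration for the synthetic recording generator
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 5-minute resting sessions sampled at 60 Hz, free breathing around
#' 13.58 breaths/min (SD 3.58) with a mean inspiratory fraction of 0.45, a
#' baseline pupil of 4.5 mm, and a phase-locked pupil component of amplitude
#' 0.15 z peaking at 220 degrees (mid-exhalation), so that pupil size is
#' smallest near inhalation onset and largest during exhalation. Blinks
#' occur at 12/min with durations of 100-400 ms; rare longer dropouts
#' exercise the removal rule.
#'
#' @param n_participants number of participants in a cohort.
#' @param session_duration session length in seconds.
#' @param rate sampling rate in Hz.
#' @param bpm_mean,bpm_sd breathing frequency (breaths/min), across cycles.
#' @param inhale_fraction_mean,inhale_fraction_sd inspiratory fraction of the
#'   cycle.
#' @param prp_amplitude amplitude of the phase-locked pupil component, in z
#'   units of the pupil noise.
#' @param prp_peak_phase phase (degrees) at which the component peaks.
#' @param noise_sd white pupil noise SD, z units.
#' @param drift_sd per-sample SD of the slow random-walk drift, z units.
#' @param blink_rate blinks per minute.
#' @param blink_duration_ms blink duration range, ms.
#' @param long_dropout_rate expected long (> 500 ms) dropouts per session.
#' @param long_dropout_ms long-dropout duration range, ms.
#' @param baseline_mm mean pupil size in mm.
#' @param mm_per_z conversion from z units to mm.
#' @param eye_noise_cor correlation of the two eyes' noise.
#' @param airflow_noise_sd airflow sensor noise SD (cycle amplitude is 1).
#' @param amplitude_jitter_sd,phase_jitter_sd between-participant SDs of the
#'   component's amplitude (z) and peak phase (degrees).
#' @param two_harmonic add a second harmonic (skewed waveform) to the
#'   phase-locked component for robustness testing.
#' @param edge_spikes inject single-sample spikes next to blink gaps to
#'   exercise rapid-change detection.
#' @param seed integer seed.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 40L,
                             session_duration = 300,
                             rate = 60,
                             bpm_mean = 13.58, bpm_sd = 3.58,
                             inhale_fraction_mean = 0.45,
                             inhale_fraction_sd = 0.05,
                             prp_amplitude = 0.15,
                             prp_peak_phase = 220,
                             noise_sd = 1.0,
                             drift_sd = 0.002,
                             blink_rate = 12,
                             blink_duration_ms = c(100, 400),
                             long_dropout_rate = 2,
                             long_dropout_ms = c(700, 1500),
                             baseline_mm = 4.5,
                             mm_per_z = 0.5,
                             eye_noise_cor = 0.8,
                             airflow_noise_sd = 0.05,
                             amplitude_jitter_sd = 0.05,
                             phase_jitter_sd = 20,
                             two_harmonic = FALSE,
                             edge_spikes = FALSE,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_participants >= 1L, cfg$session_duration > 0, cfg$rate > 0,
            cfg$bpm_mean > 0, cfg$bpm_sd >= 0,
            cfg$inhale_fraction_mean > 0.2, cfg$inhale_fraction_mean < 0.8,
            cfg$prp_peak_phase >= 0, cfg$prp_peak_phase < 360,
            cfg$noise_sd >= 0, cfg$blink_rate >= 0,
            length(cfg$blink_duration_ms) == 2L)
  class(cfg) <- "generator_config"
  cfg
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

#' Generate a synthetic airflow trace with ground-truth landmarks
#'
#' Cycle durations are drawn from a truncated normal matched to the
#' configured breathing frequency (cycles clipped to 1.2-12 s); each cycle is
#' a positive half-sine (inhalation) followed by a negative half-sine
#' (exhalation), with the inspiratory fraction drawn per cycle. Gaussian
#' sensor noise is added. Draws from the current RNG state; seed outside for
#' reproducibility.
#'
#' @param cfg a [generator_config()].
#' @return a list with `airflow` (noisy), `airflow_clean`, `time_ms`,
#'   `landmarks` (ground-truth tibble in [detect_landmarks()] layout) and
#'   `phase` (ground-truth `phase_series` at the sample times).
#' @export
generate_breathing <- function(cfg) {
  n <- round(cfg$session_duration * cfg$rate)
  t_ms <- (seq_len(n) - 1L) / cfg$rate * 1000

  # cycle durations from a truncated normal matched to the configured
  # breathing frequency (delta-method SD so breaths/min comes out right)
  dur_mean <- 60 / cfg$bpm_mean
  dur_sd <- 60 * cfg$bpm_sd / cfg$bpm_mean^2
  durs <- c()
  while (sum(durs) < cfg$session_duration + 12) {
    durs <- c(durs, rtrunc_norm(16L, dur_mean, dur_sd, 1.2, 12))
  }
  onsets <- cumsum(c(0, durs))
  k <- max(which(onsets < cfg$session_duration))
  durs <- durs[seq_len(k)]
  onsets <- onsets[seq_len(k)] * 1000
  ti <- rtrunc_norm(k, cfg$inhale_fraction_mean, cfg$inhale_fraction_sd,
                    0.2, 0.8) * durs * 1000
  te <- durs * 1000 - ti

  landmarks <- tibble::tibble(
    cycle_id = seq_len(k),
    inhalation_onset = onsets,
    inhalation_peak = onsets + ti / 2,
    exhalation_onset = onsets + ti,
    exhalation_peak = onsets + ti + te / 2,
    next_onset = onsets + ti + te)
  landmarks <- validate_cycles(landmarks)
  class(landmarks) <- c("breath_landmarks", class(landmarks))

  # exhalation amplitude scaled by ti/te so each cycle's airflow integrates
  # to zero (inhaled volume = exhaled volume); the trace then has zero mean
  # and mean-centring in the detector does not bias the zero crossings
  clean <- numeric(n)
  for (j in seq_len(k)) {
    inh <- which(t_ms >= landmarks$inhalation_onset[j] &
                   t_ms < landmarks$exhalation_onset[j])
    exh <- which(t_ms >= landmarks$exhalation_onset[j] &
                   t_ms < landmarks$next_onset[j])
    clean[inh] <- sin(pi * (t_ms[inh] - landmarks$inhalation_onset[j]) / ti[j])
    clean[exh] <- -(ti[j] / te[j]) *
      sin(pi * (t_ms[exh] - landmarks$exhalation_onset[j]) / te[j])
  }
  airflow <- clean + rnorm(n, 0, cfg$airflow_noise_sd)
  phase <- compute_phase(landmarks, t_ms)
  list(airflow = airflow, airflow_clean = clean, time_ms = t_ms,
       landmarks = landmarks, phase = phase)
}

#' Generate a pair of pupil traces locked to a respiratory phase
#'
#' The noiseless z-scale signal is
#' `amplitude * cos(phase - peak_phase)` (plus an optional second harmonic),
#' plus a slow random-walk drift. Each eye adds correlated Gaussian noise,
#' is converted to mm around the baseline, and receives shared blink gaps
#' (invalid samples, values zeroed as an eye tracker would) plus rare long
#' dropouts. Draws from the current RNG state.
#'
#' @param phase a ground-truth `phase_series` from [generate_breathing()].
#' @param cfg a [generator_config()].
#' @param amplitude,peak_phase override the cohort-level component (used for
#'   per-participant jitter); default to the config values.
#' @return a list with `left`/`right` (mm [pupil_trace()]s with blink
#'   validity), `prp_component` (z), `truth` (blink and dropout intervals).
#' @export
generate_pupil <- function(phase, cfg, amplitude = cfg$prp_amplitude,
                           peak_phase = cfg$prp_peak_phase) {
  n <- nrow(phase)
  th <- phase$phase_deg * pi / 180
  th[is.na(th)] <- 0           # outside cycles: no phase-locked drive
  comp <- amplitude * cos(th - peak_phase * pi / 180)
  if (isTRUE(cfg$two_harmonic)) {
    comp <- comp + 0.4 * amplitude * cos(2 * (th - peak_phase * pi / 180))
  }
  drift <- cumsum(rnorm(n, 0, cfg$drift_sd))
  shared <- rnorm(n)
  rho <- cfg$eye_noise_cor
  z_left <- comp + drift +
    cfg$noise_sd * (sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n))
  z_right <- comp + drift +
    cfg$noise_sd * (sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n))
  mm_left <- cfg$baseline_mm + cfg$mm_per_z * z_left
  mm_right <- cfg$baseline_mm + cfg$mm_per_z * z_right

  dur_s <- n / cfg$rate
  gap_int <- function(n_gaps, dur_range_ms) {
    if (n_gaps == 0L) return(tibble::tibble(start = integer(0), end = integer(0)))
    start_ms <- sort(runif(n_gaps, 0, dur_s * 1000))
    len_ms <- runif(n_gaps, dur_range_ms[1L], dur_range_ms[2L])
    s <- pmax(1L, floor(start_ms / 1000 * cfg$rate) + 1L)
    e <- pmin(n, s + pmax(1L, round(len_ms / 1000 * cfg$rate)) - 1L)
    tibble::tibble(start = as.integer(s), end = as.integer(e))
  }
  blinks <- gap_int(rpois(1L, cfg$blink_rate * dur_s / 60),
                    cfg$blink_duration_ms)
  dropouts <- gap_int(rpois(1L, cfg$long_dropout_rate), cfg$long_dropout_ms)

  valid <- rep(TRUE, n)
  for (i in seq_len(nrow(blinks))) valid[blinks$start[i]:blinks$end[i]] <- FALSE
  for (i in seq_len(nrow(dropouts))) valid[dropouts$start[i]:dropouts$end[i]] <- FALSE
  mm_left[!valid] <- 0
  mm_right[!valid] <- 0

  if (isTRUE(cfg$edge_spikes) && nrow(blinks) > 0L) {
    pick <- blinks$end[runif(nrow(blinks)) < 0.3] + 1L
    pick <- pick[pick <= n & valid[pmin(pick, n)]]
    mm_left[pick] <- mm_left[pick] + cfg$mm_per_z * 3
    mm_right[pick] <- mm_right[pick] + cfg$mm_per_z * 3
  }

  list(left = pupil_trace(mm_left, valid = valid, rate = cfg$rate, unit = "mm"),
       right = pupil_trace(mm_right, valid = valid, rate = cfg$rate, unit = "mm"),
       prp_component = comp,
       truth = list(blinks = blinks, dropouts = dropouts,
                    amplitude = amplitude, peak_phase = peak_phase))
}

#' Generate one synthetic recording with full ground truth
#'
#' @param cfg a [generator_config()].
#' @param participant_id,session_id,route labels for the recording.
#' @param amplitude,peak_phase participant-level component; drawn with the
#'   configured between-participant jitter when `NULL`.
#' @return a list with `recording` (a [recording()]) and `truth` (landmarks,
#'   phase series, phase-locked component, blink/dropout intervals,
#'   participant amplitude and peak phase).
#' @export
generate_recording <- function(cfg, participant_id = "p01",
                               session_id = "s01", route = "nose",
                               amplitude = NULL, peak_phase = NULL) {
  br <- generate_breathing(cfg)
  amp <- amplitude %||%
    rnorm(1L, cfg$prp_amplitude, cfg$amplitude_jitter_sd)
  pk <- peak_phase %||%
    (rnorm(1L, cfg$prp_peak_phase, cfg$phase_jitter_sd) %% 360)
  pp <- generate_pupil(br$phase, cfg, amplitude = amp, peak_phase = pk)
  data <- tibble::tibble(
    time_ms = br$time_ms,
    pupil_left = pp$left$values, pupil_right = pp$right$values,
    valid_left = pp$left$valid, valid_right = pp$right$valid,
    airflow = br$airflow)
  rec <- recording(data, participant_id = participant_id,
                   session_id = session_id, route = route, unit = "mm",
                   rate = cfg$rate)
  stopifnot(nrow(rec$data) == nrow(br$phase))   # truth consistent by construction
  list(recording = rec,
       truth = list(landmarks = br$landmarks, phase = br$phase,
                    prp_component = pp$prp_component,
                    blinks = pp$truth$blinks, dropouts = pp$truth$dropouts,
                    amplitude = amp, peak_phase = pk))
}

#' Generate a cohort of synthetic recordings
#'
#' One session per participant per route label, with per-participant jitter
#' of the phase-locked component's amplitude and peak phase. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @param routes route label(s); each participant gets one session per route.
#' @return a list of `generate_recording()` results (fields `recording`,
#'   `truth`).
#' @export
generate_cohort <- function(cfg = generator_config(), routes = "nose") {
  withr::with_seed(as.integer(cfg$seed), {
    out <- list()
    for (p in seq_len(cfg$n_participants)) {
      amp <- rnorm(1L, cfg$prp_amplitude, cfg$amplitude_jitter_sd)
      pk <- rnorm(1L, cfg$prp_peak_phase, cfg$phase_jitter_sd) %% 360
      for (r in routes) {
        out[[length(out) + 1L]] <- generate_recording(
          cfg, participant_id = sprintf("p%02d", p),
          session_id = sprintf("s_%s", r), route = r,
          amplitude = amp, peak_phase = pk)
      }
    }
    out
  })
}
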