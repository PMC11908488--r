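#' Zero-phase low-pass filter for airflow
#'
#' 4th-order Butterworth low-pass applied forward and backward
#' (zero phase, DC gain 1).
#'
#' @param x airflow time series (numeric vector).
#' @param rate sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz (default 5).
#' @return the filtered series.
#' @export
lowpass_airflow <- function(x, rate, cutoff = 5) {
  if (rate <= 2 * cutoff) stop("sampling rate must exceed twice the cutoff")
  bf <- signal::butter(4, cutoff / (rate / 2), type = "low")
  # odd-symmetric reflection padding keeps the filter settled at the edges
  n <- length(x)
  pad <- min(n - 1L, ceiling(10 * rate / cutoff))
  left <- 2 * x[1L] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Detect breathing landmarks in an airflow trace
#'
#' On the mean-centred (low-pass filtered, inspiration-positive) signal,
#' inhalation onsets are negative-to-positive zero crossings and exhalation
#' onsets positive-to-negative crossings; the inhalation peak is the airflow
#' maximum between the two, the exhalation peak (trough) the minimum before
#' the next inhalation onset. Crossings closer than `debounce_ms` to the
#' previously kept crossing are merged to suppress noise-driven micro-cycles,
#' and alternation of crossing directions is enforced. Incomplete leading and
#' trailing half-cycles are dropped.
#'
#' @param airflow low-pass filtered airflow, inspiration-positive.
#' @param rate sampling rate in Hz.
#' @param time_ms optional timestamps; defaults to a 0-based grid at `rate`.
#' @param inspiration_positive set `FALSE` to flip the sign convention.
#' @param debounce_ms minimal spacing between kept zero crossings.
#' @return a `breath_landmarks` tibble: one row per cycle with
#'   `cycle_id`, `inhalation_onset`, `inhalation_peak`, `exhalation_onset`,
#'   `exhalation_peak`, `next_onset` (ms) and validity flags (filled by
#'   [validate_cycles()]).
#' @export
detect_landmarks <- function(airflow, rate, time_ms = NULL,
                             inspiration_positive = TRUE,
                             debounce_ms = 250) {
  n <- length(airflow)
  if (is.null(time_ms)) time_ms <- (seq_len(n) - 1L) / rate * 1000
  stopifnot(length(time_ms) == n)
  s <- airflow - mean(airflow, na.rm = TRUE)
  if (!inspiration_positive) s <- -s

  pos <- s > 0
  up <- which(!pos[-n] & pos[-1L]) + 1L      # first sample of positive half
  down <- which(pos[-n] & !pos[-1L]) + 1L    # first sample of negative half
  if (length(up) == 0L && length(down) == 0L) stop("no breathing detected")

  # sub-sample crossing time by linear interpolation between the two
  # bracketing samples
  cross_t <- function(i) {
    s0 <- s[i - 1L]; s1 <- s[i]
    if (s1 == s0) return(time_ms[i])
    time_ms[i - 1L] + (0 - s0) / (s1 - s0) * (time_ms[i] - time_ms[i - 1L])
  }
  cross <- rbind(data.frame(idx = up, dir = 1L),
                 data.frame(idx = down, dir = -1L))
  cross <- cross[order(cross$idx), ]
  cross$t <- vapply(cross$idx, cross_t, numeric(1))

  # debounce, then enforce alternation of crossing directions
  kept <- integer(0)
  for (i in seq_len(nrow(cross))) {
    if (length(kept) > 0L) {
      last <- cross[tail(kept, 1L), ]
      too_close <- (cross$t[i] - last$t) < debounce_ms
      same_dir <- cross$dir[i] == last$dir
      if (too_close || same_dir) next
    }
    kept <- c(kept, i)
  }
  cross <- cross[kept, ]
  ups <- which(cross$dir == 1L)
  if (length(ups) < 2L) stop("no breathing detected")

  cycles <- list()
  for (k in seq_len(length(ups) - 1L)) {
    u0 <- ups[k]; u1 <- ups[k + 1L]
    if (u1 != u0 + 2L) next                  # needs exactly one down between
    i0 <- cross$idx[u0]; d <- cross$idx[u0 + 1L]; i1 <- cross$idx[u1]
    peak <- i0 + which.max(s[i0:d]) - 1L
    trough <- d + which.min(s[d:i1]) - 1L
    t_on <- cross$t[u0]; t_off <- cross$t[u0 + 1L]; t_next <- cross$t[u1]
    if (!(t_on < time_ms[peak] && time_ms[peak] < t_off &&
          t_off < time_ms[trough] && time_ms[trough] < t_next)) next
    cycles[[length(cycles) + 1L]] <- tibble::tibble(
      inhalation_onset = t_on, inhalation_peak = time_ms[peak],
      exhalation_onset = t_off, exhalation_peak = time_ms[trough],
      next_onset = t_next)
  }
  if (length(cycles) == 0L) stop("no complete breathing cycles detected")
  lm <- dplyr::bind_rows(cycles)
  lm <- tibble::tibble(cycle_id = seq_len(nrow(lm)), lm,
                       valid_inhale = NA, valid_exhale = NA)
  class(lm) <- c("breath_landmarks", class(lm))
  attr(lm, "rate") <- rate
  lm
}

#' Validate breathing half-cycles by duration
#'
#' Inhalations and exhalations lasting less than `min_ms` (default 500 ms) or
#' more than `max_ms` (default 6000 ms) are flagged invalid; their samples
#' get `valid = FALSE` in the phase series and contribute no observations
#' downstream.
#'
#' @param landmarks a [detect_landmarks()] table.
#' @param min_ms,max_ms valid half-breath duration range in ms.
#' @return the landmarks with `valid_inhale`/`valid_exhale` filled in.
#' @export
validate_cycles <- function(landmarks, min_ms = 500, max_ms = 6000) {
  inhale <- landmarks$exhalation_onset - landmarks$inhalation_onset
  exhale <- landmarks$next_onset - landmarks$exhalation_onset
  landmarks$valid_inhale <- inhale >= min_ms & inhale <= max_ms
  landmarks$valid_exhale <- exhale >= min_ms & exhale <= max_ms
  landmarks
}

#' Continuous respiratory phase from landmarks
#'
#' Assigns each timestamp a phase angle in `[0, 360)` by linear interpolation
#' within the four landmark segments of its cycle: inhalation onset 0,
#' inhalation peak 90, exhalation onset 180, exhalation peak 270, next
#' inhalation onset 360 (wrapping to 0). Segments are half-open so every
#' sample has a unique phase. Samples outside detected cycles, or inside a
#' half-breath flagged invalid, are marked invalid.
#'
#' @param landmarks validated [detect_landmarks()] table.
#' @param time_ms timestamps at which to evaluate the phase.
#' @return a `phase_series` tibble with `time_ms`, `phase_deg`, `cycle_id`,
#'   `valid`.
#' @export
compute_phase <- function(landmarks, time_ms) {
  k <- nrow(landmarks)
  lm <- as.matrix(landmarks[, c("inhalation_onset", "inhalation_peak",
                                "exhalation_onset", "exhalation_peak",
                                "next_onset")])
  if (any(t(apply(lm, 1L, diff)) <= 0)) {
    stop("landmark timestamps must be strictly increasing within each cycle")
  }
  phase <- rep(NA_real_, length(time_ms))
  cyc <- rep(NA_integer_, length(time_ms))
  seg_phase <- c(0, 90, 180, 270, 360)
  for (j in seq_len(k)) {
    sel <- which(time_ms >= lm[j, 1L] & time_ms < lm[j, 5L])
    if (length(sel) == 0L) next
    phase[sel] <- approx(lm[j, ], seg_phase, xout = time_ms[sel])$y %% 360
    cyc[sel] <- j
  }
  in_cycle <- !is.na(phase)
  half_valid <- rep(FALSE, length(time_ms))
  i <- which(in_cycle)
  is_inhale <- phase[i] < 180
  vi <- landmarks$valid_inhale[cyc[i]]
  ve <- landmarks$valid_exhale[cyc[i]]
  vi[is.na(vi)] <- TRUE
  ve[is.na(ve)] <- TRUE
  half_valid[i] <- ifelse(is_inhale, vi, ve)
  out <- tibble::tibble(time_ms = time_ms, phase_deg = phase,
                        cycle_id = cyc, valid = in_cycle & half_valid)
  class(out) <- c("phase_series", class(out))
  out
}

#' Breathing rate in breaths per minute
#'
#' @param landmarks validated [detect_landmarks()] table.
#' @param duration_s recording duration in seconds.
#' @return breaths per minute, counting cycles with a valid inhalation.
#' @export
breathing_rate <- function(landmarks, duration_s) {
  n <- sum(landmarks$valid_inhale, na.rm = TRUE)
  if (n == 0L) stop("no valid breathing cycles")
  n / duration_s * 60
}
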