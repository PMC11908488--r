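#' Invalidate unreliable valid stretches
#'
#' Applies the duration-based validity rules. At every stage, maximal valid
#' runs shorter than `cfg$min_valid_ms` are marked invalid, and valid islands
#' shorter than `cfg$island_valid_ms` flanked on *both* sides by invalid
#' stretches longer than `cfg$island_context_ms` are marked invalid. After
#' interpolation (`stage = "post_interpolation"`) an additional island rule
#' applies: valid runs shorter than `cfg$long_island_valid_ms` surrounded by
#' invalid stretches longer than `cfg$long_island_context_ms`.
#'
#' No valid run is ever extended; the operation is idempotent once a trace is
#' stable under the rules.
#'
#' @param trace a [pupil_trace()].
#' @param cfg a [cleaning_config()].
#' @param stage `"initial"` or `"post_interpolation"`.
#' @return the trace with updated validity.
#' @export
mark_unreliable_valid_stretches <- function(trace, cfg = cleaning_config(),
                                            stage = c("initial",
                                                      "post_interpolation")) {
  stage <- match.arg(stage)
  trace <- invalidate_short_valid(trace, cfg$min_valid_ms)
  trace <- invalidate_islands(trace, cfg$island_valid_ms,
                              cfg$island_context_ms)
  if (stage == "post_interpolation") {
    trace <- invalidate_islands(trace, cfg$long_island_valid_ms,
                                cfg$long_island_context_ms)
  }
  trace
}

invalidate_short_valid <- function(trace, min_ms) {
  runs <- logical_runs(trace$valid)
  bad <- runs$value & run_ms(runs$len, trace$rate) < min_ms
  for (i in which(bad)) trace$valid[runs$start[i]:runs$end[i]] <- FALSE
  trace
}

invalidate_islands <- function(trace, island_ms, context_ms) {
  runs <- logical_runs(trace$valid)
  n <- nrow(runs)
  if (n < 3L) return(trace)
  for (i in seq_len(n)) {
    if (!runs$value[i]) next
    if (i == 1L || i == n) next                       # needs a flank on both sides
    if (run_ms(runs$len[i], trace$rate) >= island_ms) next
    left_ok <- run_ms(runs$len[i - 1L], trace$rate) > context_ms
    right_ok <- run_ms(runs$len[i + 1L], trace$rate) > context_ms
    if (left_ok && right_ok) trace$valid[runs$start[i]:runs$end[i]] <- FALSE
  }
  trace
}

#' Remove long invalid stretches
#'
#' Invalid stretches longer than `cfg$max_blink_ms` (default 500 ms) are
#' unlikely to be blinks and are permanently removed: they are never
#' interpolated and count as invalid for the session-exclusion rule.
#'
#' @inheritParams mark_unreliable_valid_stretches
#' @return the trace with `removed` updated.
#' @export
remove_long_invalid <- function(trace, cfg = cleaning_config()) {
  runs <- logical_runs(trace$valid)
  long <- !runs$value & run_ms(runs$len, trace$rate) > cfg$max_blink_ms
  for (i in which(long)) trace$removed[runs$start[i]:runs$end[i]] <- TRUE
  trace$valid[trace$removed] <- FALSE
  trace
}

#' Interpolate short invalid gaps
#'
#' For every maximal invalid (non-removed) stretch, a buffer of
#' `cfg$buffer_frames` frames on each side is marked invalid as well, and the
#' complete stretch is filled with a piecewise cubic spline through the
#' `cfg$flank_samples` nearest valid samples on each side. If the range of
#' the filled values exceeds the range of the anchor values by more than the
#' stage tolerance (30% on the first pass, 20% on the rapid-change recheck),
#' the fill is redone with buffers of 3 and then 4 frames; if it still
#' exceeds the tolerance, a linear interpolation through the two buffer
#' frames and the three anchors on each side is used instead.
#'
#' Gaps touching the trace edge, or lacking enough valid anchors within
#' `cfg$max_anchor_gap_ms`, stay invalid.
#'
#' @inheritParams mark_unreliable_valid_stretches
#' @param mode `"first_pass"` (30% range guard) or `"recheck"` (20%).
#' @return the trace with gaps filled and marked valid + interpolated.
#' @export
interpolate_gaps <- function(trace, cfg = cleaning_config(),
                             mode = c("first_pass", "recheck")) {
  mode <- match.arg(mode)
  tol <- if (mode == "first_pass") cfg$spline_range_tolerance else
    cfg$recheck_range_tolerance
  gaps <- logical_runs(!trace$valid & !trace$removed)
  gaps <- gaps[gaps$value, , drop = FALSE]
  for (g in seq_len(nrow(gaps))) {
    trace <- fill_one_gap(trace, gaps$start[g], gaps$end[g], cfg, tol)
  }
  trace
}

# Fill one maximal invalid run [g0, g1]; no-op when unfillable.
fill_one_gap <- function(trace, g0, g1, cfg, tol) {
  n <- length(trace)
  anchor_ok <- trace$valid & !trace$removed
  max_gap_samples <- cfg$max_anchor_gap_ms / 1000 * trace$rate

  try_fill <- function(buffer) {
    e0 <- g0 - buffer
    e1 <- g1 + buffer
    if (e0 < 1L || e1 > n) return(NULL)          # touches the trace edge
    usable <- anchor_ok
    usable[e0:e1] <- FALSE                       # buffers count as invalid
    left <- which(usable[seq_len(e0 - 1L)])
    right <- if (e1 >= n) integer(0) else
      which(usable[seq.int(e1 + 1L, n)]) + e1
    if (length(left) < cfg$flank_samples ||
        length(right) < cfg$flank_samples) return(NULL)
    left <- tail(left, cfg$flank_samples)
    right <- head(right, cfg$flank_samples)
    if ((e0 - min(left)) > max_gap_samples ||
        (max(right) - e1) > max_gap_samples) return(NULL)
    anchors <- c(left, right)
    f <- splinefun(anchors, trace$values[anchors], method = "fmm")
    fill <- f(e0:e1)
    list(fill = fill, e0 = e0, e1 = e1, anchors = anchors,
         ok = diff(range(fill)) <=
           diff(range(trace$values[anchors])) * (1 + tol))
  }

  chosen <- NULL
  for (b in cfg$buffer_frames + 0:2) {           # buffers 2, 3, 4
    cand <- try_fill(b)
    if (is.null(cand)) {
      if (b == cfg$buffer_frames) return(trace)  # unfillable at base buffer
      next
    }
    if (cand$ok) { chosen <- cand; break }
    if (b == cfg$buffer_frames) chosen_base <- cand
  }

  if (is.null(chosen)) {
    # linear fallback: buffer frames keep their recorded values and anchor the
    # line together with the flank samples; only still-invalid samples are
    # overwritten
    base <- chosen_base
    buf <- setdiff(base$e0:base$e1, g0:g1)
    pts <- sort(c(base$anchors, buf))
    fill_idx <- g0:g1
    trace$values[fill_idx] <- approx(pts, trace$values[pts],
                                     xout = fill_idx)$y
    trace$valid[base$e0:base$e1] <- TRUE
    trace$interpolated[fill_idx] <- TRUE
    return(trace)
  }

  idx <- chosen$e0:chosen$e1
  trace$values[idx] <- chosen$fill
  trace$valid[idx] <- TRUE
  trace$interpolated[idx] <- TRUE
  trace
}

#' Detect rapid changes in pupil size
#'
#' Flags samples whose first difference exceeds
#' `cfg$speed_mad_multiplier` times the median absolute deviation of the
#' first differences of valid samples -- a robust speed criterion for blinks
#' or bad interpolations. Both samples of a flagged pair are marked, and the
#' mask is dilated by `cfg$buffer_frames` on each side. A constant trace
#' (MAD 0) yields no detections.
#'
#' @inheritParams mark_unreliable_valid_stretches
#' @return logical mask of samples belonging to rapid-change stretches.
#' @export
detect_rapid_changes <- function(trace, cfg = cleaning_config()) {
  stopifnot(sum(trace$valid) >= 10L)
  n <- length(trace)
  d <- c(NA_real_, diff(trace$values))
  pair_ok <- c(FALSE, trace$valid[-n] & trace$valid[-1L])
  thr <- cfg$speed_mad_multiplier * mad(d[pair_ok], na.rm = TRUE)
  hit <- which(pair_ok & !is.na(d) & abs(d) > thr & abs(d) > 0)
  mask <- rep(FALSE, n)
  if (length(hit) == 0L) return(mask)
  for (i in hit) {
    lo <- max(1L, i - 1L - cfg$buffer_frames)
    hi <- min(n, i + cfg$buffer_frames)
    mask[lo:hi] <- TRUE
  }
  mask
}

#' Re-interpolate rapid-change stretches
#'
#' Marks the samples flagged by [detect_rapid_changes()] invalid and redoes
#' the interpolation with the stricter 20% range guard.
#'
#' @inheritParams mark_unreliable_valid_stretches
#' @return the trace after the recheck.
#' @export
recheck_rapid_changes <- function(trace, cfg = cleaning_config()) {
  mask <- detect_rapid_changes(trace, cfg)
  if (!any(mask)) return(trace)
  trace$valid[mask] <- FALSE
  interpolate_gaps(trace, cfg, mode = "recheck")
}

#' Mask statistical outliers
#'
#' Valid samples smaller or larger than the mean pupil size +/-
#' `cfg$outlier_sd` times the standard deviation of the trace's valid samples
#' are marked invalid. A zero-variance trace is returned unchanged.
#'
#' @inheritParams mark_unreliable_valid_stretches
#' @return the trace with outliers invalidated.
#' @export
mask_outliers <- function(trace, cfg = cleaning_config()) {
  v <- trace$values[trace$valid]
  stopifnot(length(v) >= 2L)
  s <- sd(v)
  if (!is.finite(s) || s == 0) return(trace)
  m <- mean(v)
  out <- trace$valid &
    (trace$values < m - cfg$outlier_sd * s |
       trace$values > m + cfg$outlier_sd * s)
  trace$valid[out] <- FALSE
  trace
}

#' Average the two eyes
#'
#' Samplewise mean where both eyes are valid. Where exactly one eye is valid
#' (`mode = "either"`, the default) that eye's value is used, maximizing data
#' use; `mode = "both"` requires both eyes. Where neither is valid the sample
#' is invalid; it is removed when both eyes removed it.
#'
#' @param left,right [pupil_trace()]s of equal length and rate.
#' @param mode `"either"` or `"both"`.
#' @return the combined [pupil_trace()].
#' @export
combine_eyes <- function(left, right, mode = c("either", "both")) {
  mode <- match.arg(mode)
  if (length(left) != length(right)) stop("eye traces differ in length")
  if (left$rate != right$rate) stop("eye traces differ in sampling rate")
  both <- left$valid & right$valid
  vals <- rep(NA_real_, length(left))
  vals[both] <- (left$values[both] + right$values[both]) / 2
  valid <- both
  if (mode == "either") {
    only_l <- left$valid & !right$valid
    only_r <- right$valid & !left$valid
    vals[only_l] <- left$values[only_l]
    vals[only_r] <- right$values[only_r]
    valid <- both | only_l | only_r
  }
  out <- pupil_trace(vals, valid = valid, rate = left$rate,
                     removed = left$removed & right$removed,
                     unit = left$unit)
  out$interpolated <- left$interpolated | right$interpolated
  out
}

#' z-score pupil traces
#'
#' Transforms values to zero mean and unit standard deviation (population SD,
#' divisor n) over the pooled valid samples of the supplied traces. Pooling a
#' participant's sessions implements participant-level normalization; pass a
#' single trace for session-level scope.
#'
#' @param traces a single [pupil_trace()] or a list of traces to pool.
#' @return traces of unit `"z"` (a single trace if a single trace came in).
#' @export
zscore_trace <- function(traces) {
  single <- inherits(traces, "pupil_trace")
  if (single) traces <- list(traces)
  pooled <- unlist(lapply(traces, function(tr) tr$values[tr$valid]))
  if (length(pooled) < 2L) stop("need at least 2 valid samples to z-score")
  m <- mean(pooled)
  s <- sqrt(mean((pooled - m)^2))
  if (s == 0) stop("zero variance: constant pupil trace signals an upstream failure")
  out <- lapply(traces, function(tr) {
    tr$values <- (tr$values - m) / s
    tr$unit <- "z"
    tr
  })
  if (single) out[[1L]] else out
}

#' Downsample a trace by nearest-neighbour selection
#'
#' Selects, for every point of the target time grid, the nearest source
#' sample; values and validity flags are carried over unchanged. Upsampling
#' is refused.
#'
#' @param trace a [pupil_trace()].
#' @param target_rate target sampling rate in Hz (`<=` source rate).
#' @return the resampled [pupil_trace()].
#' @export
resample_trace <- function(trace, target_rate) {
  if (target_rate > trace$rate) stop("upsampling is not supported")
  if (target_rate == trace$rate) return(trace)
  n_out <- floor((length(trace) - 1L) * target_rate / trace$rate) + 1L
  t_out <- (seq_len(n_out) - 1L) / target_rate
  idx <- pmin(pmax(round(t_out * trace$rate) + 1L, 1L), length(trace))
  out <- pupil_trace(trace$values[idx], valid = trace$valid[idx],
                     rate = target_rate, removed = trace$removed[idx],
                     unit = trace$unit)
  out$interpolated <- trace$interpolated[idx]
  out
}

#' Run the full staged cleaning pipeline on one eye
#'
#' Fixed stage order: initial validity rules, removal of long invalid
#' stretches, spline interpolation, rapid-change recheck, post-interpolation
#' validity rules, outlier mask, finalization. After finalization every
#' sample is exactly one of valid or removed; re-running the pipeline on a
#' finalized trace is a no-op.
#'
#' @inheritParams mark_unreliable_valid_stretches
#' @return the finalized trace, with a `stage_log` attribute (a tibble of
#'   per-stage validity fractions).
#' @export
preprocess_pupil <- function(trace, cfg = cleaning_config()) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (isTRUE(trace$finalized)) return(trace)
  log <- list()
  note <- function(stage, tr) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      stage = stage, invalid_fraction = mean(!tr$valid),
      removed_fraction = mean(tr$removed),
      interpolated_fraction = mean(tr$interpolated))
  }
  note("input", trace)
  trace <- mark_unreliable_valid_stretches(trace, cfg, "initial")
  note("initial_validity_rules", trace)
  trace <- remove_long_invalid(trace, cfg)
  note("remove_long_invalid", trace)
  trace <- interpolate_gaps(trace, cfg, "first_pass")
  note("interpolate", trace)
  if (sum(trace$valid) >= 10L) {
    trace <- recheck_rapid_changes(trace, cfg)
    note("rapid_change_recheck", trace)
  }
  trace <- mark_unreliable_valid_stretches(trace, cfg, "post_interpolation")
  note("post_interpolation_validity_rules", trace)
  if (sum(trace$valid) >= 2L) {
    trace <- mask_outliers(trace, cfg)
    note("outlier_mask", trace)
  }
  trace$removed <- trace$removed | !trace$valid   # finalize
  trace$finalized <- TRUE
  note("finalized", trace)
  attr(trace, "stage_log") <- dplyr::bind_rows(log)
  trace
}
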