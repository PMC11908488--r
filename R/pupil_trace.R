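#' Construct a pupil trace
#'
#' A pupil trace is one eye's pupil time series together with the masks that
#' every cleaning stage updates: `valid` (sample currently usable) and
#' `removed` (permanently missing; never interpolated, counts as invalid for
#' the session-exclusion rule). Samples are assumed equally spaced at
#' `rate` Hz.
#'
#' @param values numeric vector of pupil sizes (px or mm). `NA` allowed.
#' @param valid logical vector; defaults to `!is.na(values)`.
#' @param rate sampling rate in Hz.
#' @param removed logical vector of permanently missing samples.
#' @param unit `"px"` or `"mm"` (or `"z"` after normalization).
#' @return an object of class `pupil_trace`.
#' @export
pupil_trace <- function(values, valid = !is.na(values), rate,
                        removed = rep(FALSE, length(values)),
                        unit = "px") {
  stopifnot(is.numeric(values), is.logical(valid), is.logical(removed),
            length(valid) == length(values),
            length(removed) == length(values),
            is.numeric(rate), length(rate) == 1L, rate > 0)
  valid <- valid & !is.na(valid) & !is.na(values)
  removed <- removed & !is.na(removed)
  valid[removed] <- FALSE
  structure(
    list(values = as.numeric(values), valid = valid, removed = removed,
         rate = as.numeric(rate), unit = unit,
         interpolated = rep(FALSE, length(values)), finalized = FALSE),
    class = "pupil_trace"
  )
}

#' @export
length.pupil_trace <- function(x) length(x$values)

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf(
    "<pupil_trace> %d samples @ %g Hz (%.1f s), unit %s\n  valid %.1f%%, removed %.1f%%, interpolated %.1f%%%s\n",
    length(x), x$rate, length(x) / x$rate, x$unit,
    100 * mean(x$valid), 100 * mean(x$removed), 100 * mean(x$interpolated),
    if (isTRUE(x$finalized)) ", finalized" else ""))
  invisible(x)
}

# maximal runs of a logical vector: tibble(start, end, len, value)
logical_runs <- function(flag) {
  r <- rle(flag)
  end <- cumsum(r$lengths)
  tibble::tibble(start = end - r$lengths + 1L, end = end,
                 len = r$lengths, value = r$values)
}

# duration of a run of k samples at `rate` Hz, in ms
run_ms <- function(len, rate) len / rate * 1000

#' Fraction of unusable samples in a trace
#'
#' Returns the fraction of samples that are invalid or removed. A session is
#' excluded when this fraction exceeds the configured maximum (default 30%)
#' for *both* eyes; see [session_excluded()].
#'
#' @param trace a [pupil_trace()].
#' @return fraction in `[0, 1]`.
#' @export
validity_fraction <- function(trace) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (length(trace) == 0L) stop("empty trace")
  mean(!trace$valid)
}

#' Should a session be excluded for too much invalid pupil data?
#'
#' A session is dropped when, after interpolation, more than
#' `cfg$max_invalid_fraction` of samples are invalid for both eyes. One good
#' eye keeps the session.
#'
#' @param left,right the two eyes' finalized [pupil_trace()]s.
#' @param cfg a [cleaning_config()].
#' @return `TRUE` if the session should be excluded.
#' @export
session_excluded <- function(left, right, cfg = cleaning_config()) {
  validity_fraction(left) > cfg$max_invalid_fraction &&
    validity_fraction(right) > cfg$max_invalid_fraction
}

#' Cleaning parameters for pupil preprocessing
#'
#' Defaults implement the staged cleaning rules used throughout the package:
#' valid stretches shorter than 250 ms are unreliable; valid islands shorter
#' than 500 ms surrounded by more than 2 s of invalid data (and, after
#' interpolation, islands shorter than 1000 ms surrounded by more than 5 s)
#' are unreliable; invalid stretches longer than 500 ms are unlikely to be
#' blinks and are removed rather than interpolated; spline fills may not
#' exceed the anchor range by more than 30% (20% on the rapid-change
#' recheck); samples outside mean +/- 3 SD are masked; sessions with more
#' than 30% invalid data in both eyes are excluded.
#'
#' @param min_valid_ms minimum duration of a reliable valid stretch (ms).
#' @param island_valid_ms,island_context_ms valid islands shorter than
#'   `island_valid_ms` flanked on both sides by invalid stretches longer
#'   than `island_context_ms` are invalidated.
#' @param long_island_valid_ms,long_island_context_ms the additional island
#'   rule applied after interpolation.
#' @param max_blink_ms invalid stretches longer than this are removed.
#' @param buffer_frames frames marked invalid on each side of a gap before
#'   interpolation.
#' @param spline_range_tolerance,recheck_range_tolerance allowed fractional
#'   excess of the filled range over the anchor range (first pass/recheck).
#' @param flank_samples valid anchor samples used on each side of a gap.
#' @param max_anchor_gap_ms anchors farther than this from the gap make it
#'   unfillable.
#' @param outlier_sd the +/- k SD outlier mask.
#' @param max_invalid_fraction session-exclusion threshold.
#' @param speed_mad_multiplier rapid-change threshold in units of the MAD of
#'   first differences.
#' @return a list of class `cleaning_config`.
#' @export
cleaning_config <- function(min_valid_ms = 250,
                            island_valid_ms = 500,
                            island_context_ms = 2000,
                            long_island_valid_ms = 1000,
                            long_island_context_ms = 5000,
                            max_blink_ms = 500,
                            buffer_frames = 2L,
                            spline_range_tolerance = 0.30,
                            recheck_range_tolerance = 0.20,
                            flank_samples = 3L,
                            max_anchor_gap_ms = 2000,
                            outlier_sd = 3.0,
                            max_invalid_fraction = 0.30,
                            speed_mad_multiplier = 16) {
  cfg <- list(min_valid_ms = min_valid_ms,
              island_valid_ms = island_valid_ms,
              island_context_ms = island_context_ms,
              long_island_valid_ms = long_island_valid_ms,
              long_island_context_ms = long_island_context_ms,
              max_blink_ms = max_blink_ms,
              buffer_frames = as.integer(buffer_frames),
              spline_range_tolerance = spline_range_tolerance,
              recheck_range_tolerance = recheck_range_tolerance,
              flank_samples = as.integer(flank_samples),
              max_anchor_gap_ms = max_anchor_gap_ms,
              outlier_sd = outlier_sd,
              max_invalid_fraction = max_invalid_fraction,
              speed_mad_multiplier = speed_mad_multiplier)
  durs <- c(cfg$min_valid_ms, cfg$island_valid_ms, cfg$island_context_ms,
            cfg$long_island_valid_ms, cfg$long_island_context_ms,
            cfg$max_blink_ms, cfg$max_anchor_gap_ms)
  stopifnot(all(durs > 0), cfg$spline_range_tolerance > 0,
            cfg$recheck_range_tolerance > 0, cfg$outlier_sd > 0,
            cfg$max_invalid_fraction > 0, cfg$max_invalid_fraction < 1,
            cfg$buffer_frames >= 1L, cfg$flank_samples >= 2L)
  class(cfg) <- "cleaning_config"
  cfg
}
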