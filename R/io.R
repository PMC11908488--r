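#' Construct a recording
#'
#' A recording is a synchronized multi-channel session: per-eye pupil size
#' and validity flags plus airflow, on a common, strictly increasing
#' millisecond time base.
#'
#' @param data a data frame with columns `time_ms`, `pupil_left`,
#'   `pupil_right`, `valid_left`, `valid_right`, `airflow`.
#' @param participant_id,session_id identifiers.
#' @param route breathing route: `"nose"`, `"mouth"` or `"n/a"`.
#' @param unit pupil unit, `"px"` or `"mm"`.
#' @param rate sampling rate in Hz; inferred from the median timestamp
#'   spacing when `NULL`, and checked against it (within 1%) otherwise.
#' @return an object of class `prp_recording`.
#' @export
recording <- function(data, participant_id = "p01", session_id = "s01",
                      route = c("n/a", "nose", "mouth"), unit = c("px", "mm"),
                      rate = NULL) {
  route <- match.arg(route)
  unit <- match.arg(unit)
  req <- c("time_ms", "pupil_left", "pupil_right", "valid_left",
           "valid_right", "airflow")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  data <- tibble::as_tibble(data)[req]
  if (nrow(data) < 2L) stop("a recording needs at least 2 samples")
  dt <- diff(data$time_ms)
  if (any(dt <= 0)) stop("format error: timestamps must be strictly increasing")
  implied <- 1000 / median(dt)
  if (is.null(rate)) {
    rate <- implied
  } else if (abs(rate - implied) / rate > 0.01) {
    stop(sprintf(
      "sampling_rate %g Hz inconsistent with median timestamp spacing (%.3g Hz)",
      rate, implied))
  }
  data$valid_left <- as.logical(data$valid_left) & !is.na(data$pupil_left)
  data$valid_right <- as.logical(data$valid_right) & !is.na(data$pupil_right)
  data$valid_left[is.na(data$valid_left)] <- FALSE
  data$valid_right[is.na(data$valid_right)] <- FALSE
  structure(list(participant_id = participant_id, session_id = session_id,
                 route = route, unit = unit, rate = rate, data = data),
            class = "prp_recording")
}

#' @export
print.prp_recording <- function(x, ...) {
  cat(sprintf(
    "<prp_recording> %s/%s route=%s: %d samples @ %.4g Hz (%.1f s), unit %s\n",
    x$participant_id, x$session_id, x$route, nrow(x$data), x$rate,
    (max(x$data$time_ms) - min(x$data$time_ms)) / 1000, x$unit))
  invisible(x)
}

#' Read a recording from the canonical CSV layout
#'
#' The canonical layout is a UTF-8 comma-separated table with a header row
#' and the columns `time_ms`, `pupil_left`, `pupil_right`, `valid_left`,
#' `valid_right`, `airflow`; session metadata (participant, session, route,
#' unit, sampling rate) lives in `#key: value` comment lines before the
#' header. Empty numeric cells become missing values with the validity flag
#' forced to `FALSE`. Rows are never reordered or dropped.
#'
#' @param path path to a recording CSV.
#' @param schema optional named character vector mapping canonical column
#'   names to the names actually used in the file, e.g.
#'   `c(pupil_left = "LPD")`.
#' @return a [recording()].
#' @export
read_recording <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_header_meta(path)
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      names(df)[names(df) == schema[[canonical]]] <- canonical
    }
  }
  recording(df,
            participant_id = meta$participant_id %||% "unknown",
            session_id = meta$session_id %||% "unknown",
            route = meta$route %||% "n/a",
            unit = meta$unit %||% "px",
            rate = if (!is.null(meta$sampling_rate))
              as.numeric(meta$sampling_rate) else NULL)
}

read_header_meta <- function(path) {
  meta <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !startsWith(line, "#")) break
    kv <- sub("^#\\s*", "", line)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    if (nzchar(key)) meta[[key]] <- val
  }
  meta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording to the canonical CSV layout
#'
#' @param rec a [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "prp_recording"))
  hdr <- c(sprintf("#participant_id: %s", rec$participant_id),
           sprintf("#session_id: %s", rec$session_id),
           sprintf("#route: %s", rec$route),
           sprintf("#unit: %s", rec$unit),
           sprintf("#sampling_rate: %.10g", rec$rate))
  df <- rec$data
  df$valid_left <- as.integer(df$valid_left)
  df$valid_right <- as.integer(df$valid_right)
  fmt <- function(x) {
    out <- character(length(x))
    ok <- !is.na(x)
    out[ok] <- format(x[ok], digits = 15, trim = TRUE, scientific = FALSE)
    out          # missing-value token: empty cell
  }
  chr <- vapply(df, fmt, character(nrow(df)))
  writeLines(hdr, path)
  suppressWarnings(
    write.table(chr, path, sep = ",", row.names = FALSE, quote = FALSE,
                append = TRUE, col.names = names(df)))
  invisible(path)
}

#' Write a phase-binned results table as TSV
#'
#' One row per (participant, session, bin); columns `participant`, `session`,
#' `bin_index` (0-17), `mean_z_pupil`, `derivative_z`, `n_observations`.
#'
#' @param table a data frame with the columns above.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  req <- c("participant", "session", "bin_index", "mean_z_pupil",
           "derivative_z", "n_observations")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols) > 0L) {
    stop("results table missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  table <- as.data.frame(table)[req]
  if (nrow(table) > 0L) {
    stopifnot(all(table$bin_index %in% 0:17), all(table$n_observations >= 0))
  }
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path path to the TSV.
#' @return a tibble.
#' @export
read_results <- function(path) {
  tibble::as_tibble(read.csv(path, sep = "\t"))
}
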