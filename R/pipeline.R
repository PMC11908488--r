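#' Configuration for an end-to-end pipeline run
#'
#' Either `simulate` (a [generator_config()]) or `inputs` (paths to canonical
#' recording CSVs) must be supplied.
#'
#' @param simulate a [generator_config()] for synthetic cohorts, or `NULL`.
#' @param inputs character vector of recording CSV paths, or `NULL`.
#' @param routes route labels for simulated cohorts.
#' @param cleaning a [cleaning_config()].
#' @param n_bins number of phase bins (default 18).
#' @param n_permutations permutations for the sign-flip test (default 10000).
#' @param alpha significance level for reporting (default 0.05).
#' @param permutation_unit `"samples"` (pool jointly valid samples across
#'   participants within a condition; matches per-bin observation counts in
#'   the tens of thousands) or `"participant_means"`.
#' @param seed integer seed governing all randomness of the run.
#' @return a list of class `run_config`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL, routes = "nose",
                       cleaning = cleaning_config(), n_bins = 18L,
                       n_permutations = 10000L, alpha = 0.05,
                       permutation_unit = c("samples", "participant_means"),
                       seed = 1L) {
  permutation_unit <- match.arg(permutation_unit)
  if (is.null(simulate) && is.null(inputs)) {
    stop("run_config needs either a simulate block or input paths")
  }
  stopifnot(n_bins >= 2L, alpha > 0, alpha < 1, n_permutations >= 1L)
  if (!is.null(inputs) && !all(file.exists(inputs))) {
    stop("missing input file(s): ",
         paste(inputs[!file.exists(inputs)], collapse = ", "))
  }
  structure(list(simulate = simulate, inputs = inputs, routes = routes,
                 cleaning = cleaning, n_bins = as.integer(n_bins),
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 permutation_unit = permutation_unit,
                 seed = as.integer(seed)),
            class = "run_config")
}

# preprocess one recording: clean both eyes, QC, respiratory phase
process_session <- function(rec, cfg) {
  left <- preprocess_pupil(
    pupil_trace(rec$data$pupil_left, valid = rec$data$valid_left,
                rate = rec$rate, unit = rec$unit), cfg$cleaning)
  right <- preprocess_pupil(
    pupil_trace(rec$data$pupil_right, valid = rec$data$valid_right,
                rate = rec$rate, unit = rec$unit), cfg$cleaning)
  excluded <- session_excluded(left, right, cfg$cleaning)
  qc <- tibble::tibble(
    participant = rec$participant_id, session = rec$session_id,
    route = rec$route,
    invalid_left = validity_fraction(left),
    invalid_right = validity_fraction(right),
    excluded = excluded,
    exclusion_rule = if (excluded) sprintf(
      "more than %.0f%% invalid pupil data for both eyes",
      100 * cfg$cleaning$max_invalid_fraction) else NA_character_)
  if (excluded) return(list(qc = qc))

  combined <- combine_eyes(left, right)
  flow <- lowpass_airflow(rec$data$airflow, rate = rec$rate)
  landmarks <- validate_cycles(detect_landmarks(flow, rate = rec$rate,
                                                time_ms = rec$data$time_ms))
  phase <- compute_phase(landmarks, rec$data$time_ms)
  list(qc = qc, combined = combined, landmarks = landmarks, phase = phase,
       participant = rec$participant_id, session = rec$session_id,
       route = rec$route,
       duration_s = diff(range(rec$data$time_ms)) / 1000)
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: per-eye staged cleaning, session exclusion, eye
#' averaging, participant-level z-scoring, airflow filtering and landmark
#' detection, phase construction, phase binning, the sign-flip
#' maximum-statistic permutation test per condition, per-participant circular
#' summaries with the group Rayleigh test, the per-bin pupil derivative, and
#' a repeated-measures ANOVA (phase, or phase x route when several routes are
#' present). Deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @return a `run_report` list: `qc`, `breathing` (per-session rates),
#'   `binned` (per participant x session x bin table), `group_bins` (group
#'   means per condition), `permutation` (per condition), `circular` (per
#'   condition: directions, Rayleigh, proportion toward exhalation),
#'   `derivative`, `anova`, `config` echo and `stage_order`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  recs <- if (!is.null(config$simulate)) {
    lapply(generate_cohort(config$simulate, routes = config$routes),
           `[[`, "recording")
  } else {
    lapply(config$inputs, read_recording)
  }

  sessions <- lapply(recs, process_session, cfg = config)
  qc <- dplyr::bind_rows(lapply(sessions, `[[`, "qc"))
  sessions <- Filter(function(s) !s$qc$excluded, sessions)
  if (length(sessions) == 0L) {
    stop("all sessions excluded by QC:\n",
         paste(utils::capture.output(print(as.data.frame(qc))), collapse = "\n"))
  }

  # participant-level z-scoring pools each participant's retained sessions
  by_part <- split(seq_along(sessions),
                   vapply(sessions, `[[`, "", "participant"))
  for (idx in by_part) {
    zs <- zscore_trace(lapply(sessions[idx], `[[`, "combined"))
    for (i in seq_along(idx)) sessions[[idx[i]]]$z <- zs[[i]]
  }

  breathing <- dplyr::bind_rows(lapply(sessions, function(s) tibble::tibble(
    participant = s$participant, session = s$session, route = s$route,
    breaths_per_min = breathing_rate(s$landmarks, s$duration_s),
    pct_breath_invalid = 100 *
      mean(!s$phase$valid[!is.na(s$phase$cycle_id)]))))

  samples <- dplyr::bind_rows(lapply(sessions, function(s) tibble::tibble(
    participant = s$participant, session = s$session, route = s$route,
    z = s$z$values,
    bin_index = assign_bins(s$phase$phase_deg, config$n_bins),
    joint_valid = s$z$valid & s$phase$valid)))
  samples <- dplyr::filter(samples, .data$joint_valid, !is.na(.data$bin_index))

  binned <- bin_means(samples$z, samples$bin_index,
                      groups = samples[c("participant", "session", "route")],
                      n_bins = config$n_bins)
  deriv <- dplyr::bind_rows(lapply(sessions, function(s) dplyr::bind_cols(
    tibble::tibble(participant = s$participant, session = s$session,
                   route = s$route),
    derivative_by_bin(s$z$values, s$z$valid, s$phase, config$n_bins))))
  binned <- dplyr::left_join(
    binned, deriv[c("participant", "session", "bin_index", "derivative_z",
                    "n_cycles")],
    by = c("participant", "session", "bin_index"))

  routes <- sort(unique(samples$route))
  permutation <- list()
  circular <- list()
  group_bins <- list()
  centers <- bin_centers(config$n_bins)
  for (r in routes) {
    sub <- dplyr::filter(samples, .data$route == r)
    obs <- if (config$permutation_unit == "samples") {
      split(sub$z, factor(sub$bin_index, levels = 0:(config$n_bins - 1L)))
    } else {
      pm <- bin_means(sub$z, sub$bin_index,
                      groups = sub["participant"], n_bins = config$n_bins)
      pm <- dplyr::filter(pm, !is.na(.data$mean_z_pupil))
      split(pm$mean_z_pupil,
            factor(pm$bin_index, levels = 0:(config$n_bins - 1L)))
    }
    permutation[[r]] <- signflip_max_t_test(
      obs, n_permutations = config$n_permutations, seed = config$seed)

    pb <- bin_means(sub$z, sub$bin_index, groups = sub["participant"],
                    n_bins = config$n_bins)
    dirs <- vapply(split(pb, pb$participant), function(d) {
      d <- d[!is.na(d$mean_z_pupil), ]
      if (nrow(d) == 0L || all(d$mean_z_pupil == 0)) return(NA_real_)
      suppressWarnings(
        circular_mean_direction(d$mean_z_pupil, centers[d$bin_index + 1L]))
    }, numeric(1))
    dirs <- dirs[!is.na(dirs)]
    circular[[r]] <- list(
      mean_direction_deg = as.list(dirs),
      group_direction_deg = suppressWarnings(circular_mean_direction(
        rep(1, length(dirs)), dirs)),
      rayleigh = if (length(dirs) >= 3L) rayleigh_test(dirs) else
        list(n = length(dirs), R = NA_real_, z = NA_real_, p = NA_real_),
      proportion_toward_exhalation = proportion_toward_exhalation(dirs))

    gm <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(binned, .data$route == r),
                      .data$bin_index),
      mean_z_pupil = mean(.data$mean_z_pupil, na.rm = TRUE),
      derivative_z = mean(.data$derivative_z, na.rm = TRUE),
      n_participants = dplyr::n_distinct(.data$participant),
      .groups = "drop")
    gm$bin_center_deg <- centers[gm$bin_index + 1L]
    group_bins[[r]] <- gm
  }

  anova <- tryCatch({
    cell <- dplyr::summarise(
      dplyr::group_by(binned, .data$participant, .data$route, .data$bin_index),
      mean_z_pupil = mean(.data$mean_z_pupil), .groups = "drop")
    if (length(routes) >= 2L) {
      rm_anova(cell, dv = "mean_z_pupil", subject = "participant",
               within = c("bin_index", "route"))
    } else {
      rm_anova(cell, dv = "mean_z_pupil", subject = "participant",
               within = "bin_index")
    }
  }, error = function(e) list(error = conditionMessage(e)))

  report <- list(
    stage_order = c("initial_validity_rules", "remove_long_invalid",
                    "interpolate", "rapid_change_recheck",
                    "post_interpolation_validity_rules", "outlier_mask",
                    "exclusion_check", "eye_averaging", "zscore",
                    "breath_phase", "bin_aggregate", "inference"),
    config = list(n_bins = config$n_bins,
                  n_permutations = config$n_permutations,
                  alpha = config$alpha,
                  permutation_unit = config$permutation_unit,
                  seed = config$seed),
    qc = qc, breathing = breathing, binned = binned,
    group_bins = group_bins, permutation = permutation, circular = circular,
    anova = anova)
  class(report) <- "run_report"
  report
}

#' Write a run report to disk
#'
#' Writes `report.json` (the full report), `results.tsv` (the per
#' participant x session x bin table via [write_results()]) and
#' `qc.tsv` to `dir`. Identical config and seed produce byte-identical
#' output.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- report$binned
  res <- tibble::tibble(participant = res$participant, session = res$session,
                        bin_index = res$bin_index,
                        mean_z_pupil = res$mean_z_pupil,
                        derivative_z = res$derivative_z,
                        n_observations = res$n_observations)
  write_results(res, file.path(dir, "results.tsv"))
  utils::write.table(as.data.frame(report$qc), file.path(dir, "qc.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  json <- report
  json$anova <- serialize_anova(report$anova)
  json$permutation <- lapply(report$permutation, as.data.frame)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(dir)
}

serialize_anova <- function(a) {
  if (is.null(a) || !inherits(a, "anova_result")) return(a)
  list(table = if (!is.null(a$table)) as.data.frame(a$table),
       fallback = a$fallback, n_subjects = a$n_subjects,
       dropped_subjects = a$dropped_subjects)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d session(s), %d excluded\n",
              nrow(x$qc), sum(x$qc$excluded)))
  for (r in names(x$permutation)) {
    perm <- x$permutation[[r]]
    circ <- x$circular[[r]]
    sig <- sum(perm$p_fwe < x$config$alpha)
    pmin_txt <- if (any(perm$p_fwe == 0))
      sprintf("< %g", 1 / attr(perm, "n_permutations")) else
        sprintf("= %g", min(perm$p_fwe))
    cat(sprintf(
      "  %s: %d/%d bins significant (min p_fwe %s); group direction %.1f deg; Rayleigh p = %.3g; toward exhalation %.2f\n",
      r, sig, nrow(perm), pmin_txt, circ$group_direction_deg,
      circ$rayleigh$p, circ$proportion_toward_exhalation))
  }
  invisible(x)
}
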