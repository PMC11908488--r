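#' Assign respiratory-phase bins
#'
#' Partitions `[0, 360)` into `n_bins` contiguous half-open sectors (default
#' 18 bins of 20 degrees) and returns the 0-based bin index of each phase
#' sample: `floor(phase / (360 / n_bins))`.
#'
#' @param phase_deg phase angles in degrees.
#' @param n_bins number of bins (default 18).
#' @return integer bin indices in `0:(n_bins - 1)`; `NA` phase stays `NA`.
#' @export
assign_bins <- function(phase_deg, n_bins = 18L) {
  idx <- floor((phase_deg %% 360) / (360 / n_bins))
  as.integer(pmin(idx, n_bins - 1L))
}

#' Bin centre angles in degrees
#'
#' @param n_bins number of bins.
#' @return centres at 10, 30, ..., 350 degrees for the default 18 bins.
#' @export
bin_centers <- function(n_bins = 18L) (seq_len(n_bins) - 0.5) * 360 / n_bins

#' Per-bin means of normalized pupil size
#'
#' Averages jointly valid z-scored pupil samples within each phase bin,
#' optionally per grouping keys (participant, session, condition). Bins with
#' zero observations are kept with `NA` mean and count 0.
#'
#' @param z z-scored pupil values.
#' @param bins bin indices from [assign_bins()] (`NA` = invalid sample).
#' @param groups optional data frame of grouping keys, one row per sample.
#' @param n_bins number of bins.
#' @return a tibble with the group keys, `bin_index`, `mean_z_pupil`,
#'   `n_observations`.
#' @export
bin_means <- function(z, bins, groups = NULL, n_bins = 18L) {
  df <- tibble::tibble(z = z, bin_index = bins)
  if (!is.null(groups)) df <- dplyr::bind_cols(tibble::as_tibble(groups), df)
  keys <- setdiff(names(df), "z")
  df <- dplyr::filter(df, !is.na(.data$bin_index), !is.na(.data$z))
  out <- dplyr::summarise(dplyr::group_by(df, dplyr::across(dplyr::all_of(keys))),
                          mean_z_pupil = mean(.data$z),
                          n_observations = dplyr::n(), .groups = "drop")
  # complete the bin grid so empty bins are explicit
  grid <- if (is.null(groups)) tibble::tibble(bin_index = 0:(n_bins - 1L)) else
    tidyr::crossing(dplyr::distinct(tibble::as_tibble(groups)),
                    bin_index = 0:(n_bins - 1L))
  out <- dplyr::left_join(grid, out, by = keys)
  out$n_observations[is.na(out$n_observations)] <- 0L
  out
}

#' Pupil-size derivative per phase bin
#'
#' For every breathing cycle, the differences between consecutive jointly
#' valid pupil samples are summed within the phase bin of the pair's second
#' sample; the per-bin sums are then averaged over cycles. Within one cycle
#' the per-bin sums telescope to the cycle's endpoint pupil difference.
#' Pairs spanning invalid samples or cycle boundaries are dropped.
#'
#' @param values pupil values (z-scored).
#' @param valid logical pupil validity per sample.
#' @param phase a `phase_series` from [compute_phase()].
#' @param n_bins number of bins.
#' @return a tibble with `bin_index`, `derivative_z` (mean per-cycle summed
#'   change) and `n_cycles`.
#' @export
derivative_by_bin <- function(values, valid, phase, n_bins = 18L) {
  n <- length(values)
  stopifnot(nrow(phase) == n, length(valid) == n)
  ok <- valid & phase$valid
  pair <- which(ok[-1L] & ok[-n] &
                  phase$cycle_id[-1L] == phase$cycle_id[-n]) + 1L
  d <- values[pair] - values[pair - 1L]
  bin <- assign_bins(phase$phase_deg[pair], n_bins)
  cyc <- phase$cycle_id[pair]
  sums <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(cycle_id = cyc, bin_index = bin, d = d),
                    .data$cycle_id, .data$bin_index),
    change = sum(.data$d), .groups = "drop")
  out <- dplyr::summarise(dplyr::group_by(sums, .data$bin_index),
                          derivative_z = mean(.data$change),
                          n_cycles = dplyr::n(), .groups = "drop")
  grid <- tibble::tibble(bin_index = 0:(n_bins - 1L))
  out <- dplyr::left_join(grid, out, by = "bin_index")
  out$n_cycles[is.na(out$n_cycles)] <- 0L
  out
}

# one-sample t from sufficient statistics; s = 0 cases per the documented
# convention: t = +/-Inf when the mean is nonzero, 0 when it is zero
t_from_sums <- function(s1, s2, n) {
  m <- s1 / n
  v <- pmax((s2 - n * m^2) / (n - 1), 0)
  t <- ifelse(v > 0, m / sqrt(v / n), ifelse(m == 0, 0, sign(m) * Inf))
  as.numeric(t)
}

#' Sign-flip maximum-statistic permutation test
#'
#' Tests, for each phase bin, whether the mean normalized pupil size differs
#' from zero, controlling the family-wise error rate across bins. The
#' observed statistic per bin is the one-sample t, `t = mean / (sd / sqrt(n))`.
#' The null is generated by randomly flipping the sign of every observation
#' independently; for each of `n_permutations` permutations the maximum
#' absolute t across bins is recorded, and the FWE-corrected p-value of a bin
#' is the proportion of permuted maxima greater than or equal to its observed
#' absolute t (no smoothing, so p = 0 is possible and is reported as
#' `< 1/n_permutations` in printed output).
#'
#' @param observations list of numeric vectors, one per bin (each `n >= 2`).
#' @param n_permutations number of permutations (default 10000).
#' @param seed integer seed; results are deterministic given the seed.
#' @return a tibble with `bin_index`, `n`, `t_observed`, `p_fwe` and
#'   `p_uncorrected` (per-bin p from the same null draws), with the null
#'   max-|t| distribution summary, seed and permutation count as attributes.
#' @export
signflip_max_t_test <- function(observations, n_permutations = 10000L,
                                seed = 1L) {
  stopifnot(is.list(observations), length(observations) >= 1L,
            all(vapply(observations, length, 1L) >= 2L))
  nb <- length(observations)
  n_permutations <- as.integer(n_permutations)
  t_obs <- vapply(observations, function(x)
    t_from_sums(sum(x), sum(x^2), length(x)), numeric(1))

  max_t <- rep(0, n_permutations)
  exceed <- integer(nb)     # per-bin null exceedances for p_uncorrected
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(nb)) {
      x <- observations[[b]]
      n <- length(x)
      s2 <- sum(x^2)
      chunk <- max(1L, min(n_permutations, floor(8e6 / n)))
      done <- 0L
      while (done < n_permutations) {
        m <- min(chunk, n_permutations - done)
        signs <- matrix(2 * (runif(n * m) > 0.5) - 1, nrow = n)
        s1 <- as.numeric(crossprod(signs, x))
        tb <- abs(t_from_sums(s1, s2, n))
        exceed[b] <- exceed[b] + sum(tb >= abs(t_obs[b]))
        idx <- done + seq_len(m)
        max_t[idx] <- pmax(max_t[idx], tb)
        done <- done + m
      }
    }
  })
  p_fwe <- vapply(abs(t_obs), function(t0) mean(max_t >= t0), numeric(1))
  out <- tibble::tibble(
    bin_index = seq_len(nb) - 1L,
    n = vapply(observations, length, 1L),
    t_observed = t_obs,
    p_fwe = p_fwe,
    p_uncorrected = exceed / n_permutations)
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- as.integer(seed)
  attr(out, "null_max_t") <- stats::quantile(
    max_t, c(0.5, 0.9, 0.95, 0.99), names = TRUE)
  class(out) <- c("permutation_result", class(out))
  out
}

#' Weighted circular mean direction
#'
#' Direction of the resultant vector `sum(w * exp(1i * theta))`, with the
#' per-bin mean normalized pupil sizes as weights (used as-is, so negative
#' weights point away from their bin) and the bin centre angles as
#' directions. Summarizes where on the breathing cycle pupil size peaks.
#'
#' @param weights per-bin weights (e.g. mean z-scored pupil size).
#' @param angles_deg bin angles in degrees.
#' @param tol resultant lengths below `tol * sum(|w|)` are treated as a zero
#'   resultant: the direction is undefined and `NA` is returned with a
#'   warning.
#' @return direction in `[0, 360)` degrees, or `NA` for a zero resultant.
#' @export
circular_mean_direction <- function(weights, angles_deg, tol = 1e-12) {
  stopifnot(length(weights) == length(angles_deg))
  if (all(weights == 0)) stop("at least one nonzero weight is required")
  th <- angles_deg * pi / 180
  re <- sum(weights * cos(th))
  im <- sum(weights * sin(th))
  if (sqrt(re^2 + im^2) <= tol * sum(abs(weights))) {
    warning("zero resultant vector: mean direction undefined")
    return(NA_real_)
  }
  (atan2(im, re) * 180 / pi) %% 360
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of directions is uniformly distributed on the
#' circle, from the mean resultant length `R`. The p-value uses the standard
#' series approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))`.
#'
#' @param directions_deg directions in degrees (`n >= 3`).
#' @return a list with `n`, `R`, `z` (`= n R^2`) and `p`.
#' @export
rayleigh_test <- function(directions_deg) {
  directions_deg <- directions_deg[!is.na(directions_deg)]
  n <- length(directions_deg)
  if (n < 3L) stop("Rayleigh test needs at least 3 directions")
  th <- directions_deg * pi / 180
  R <- Mod(sum(exp(1i * th))) / n
  z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * R)^2)) - (1 + 2 * n))
  list(n = n, R = R, z = z, p = min(p, 1))
}

#' Proportion of mean directions pointing toward exhalation
#'
#' The exhalation sector is `[180, 360)` degrees, matching the phase
#' construction (exhalation onset at 180 degrees).
#'
#' @param directions_deg per-participant mean directions in degrees.
#' @return fraction in `[0, 1]`.
#' @export
proportion_toward_exhalation <- function(directions_deg) {
  directions_deg <- directions_deg[!is.na(directions_deg)]
  stopifnot(length(directions_deg) >= 1L)
  mean(directions_deg %% 360 >= 180)
}

#' Mean absolute pupil size in equal time bins
#'
#' Divides the recording into `n_bins` equal-duration time bins and averages
#' the valid samples in each; used for the time x route analysis of absolute
#' pupil size (mm).
#'
#' @param trace a finalized [pupil_trace()] in mm.
#' @param n_bins number of time bins (default 18).
#' @return a tibble with `bin_index` (0-based), `mean_pupil`,
#'   `n_observations`; empty bins have `NA` mean.
#' @export
time_bin_means <- function(trace, n_bins = 18L) {
  n <- length(trace)
  bin <- pmin(floor((seq_len(n) - 1L) / n * n_bins), n_bins - 1L)
  df <- tibble::tibble(bin_index = as.integer(bin), v = trace$values,
                       ok = trace$valid)
  df <- dplyr::filter(df, .data$ok)
  out <- dplyr::summarise(dplyr::group_by(df, .data$bin_index),
                          mean_pupil = mean(.data$v),
                          n_observations = dplyr::n(), .groups = "drop")
  grid <- tibble::tibble(bin_index = 0:(n_bins - 1L))
  out <- dplyr::left_join(grid, out, by = "bin_index")
  out$n_observations[is.na(out$n_observations)] <- 0L
  out
}
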