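test_that("phase bins are half-open 20-degree sectors", {
  expect_equal(assign_bins(c(0, 19.999, 20, 350, 359.999)),
               c(0L, 0L, 1L, 17L, 17L))
  expect_true(is.na(assign_bins(NA_real_)))
  # uniform phases fill bins evenly (binomial 4 SD bound)
  ph <- withr::with_seed(21, runif(1e6, 0, 360))
  counts <- table(assign_bins(ph))
  expected <- 1e6 / 18
  bound <- 4 * sqrt(1e6 * (1 / 18) * (17 / 18))
  expect_length(counts, 18L)
  expect_true(all(abs(counts - expected) < bound))
})

test_that("bin means recover a cosine modulation", {
  ph <- seq(0, 360 - 1e-9, length.out = 2e5)
  z <- cos((ph - 180) * pi / 180)
  out <- bin_means(z, assign_bins(ph))
  # numeric-integration oracle per bin: average of cos over the 20-deg sector
  oracle <- vapply(0:17, function(k) {
    th <- seq(k * 20, (k + 1) * 20, length.out = 2000) - 180
    mean(cos(th * pi / 180))
  }, numeric(1))
  expect_equal(out$mean_z_pupil, oracle, tolerance = 1e-3)
  expect_equal(sum(out$n_observations), length(z))

  flat <- bin_means(rep(0, 1000), assign_bins(runif(1000, 0, 360)))
  expect_true(all(flat$mean_z_pupil[flat$n_observations > 0] == 0))

  only3 <- bin_means(c(1, 2, 3), c(3L, 3L, 3L))
  expect_equal(only3$mean_z_pupil[only3$bin_index == 3], 2)
  expect_equal(sum(only3$n_observations == 0), 17L)
})

test_that("per-bin derivatives telescope to cycle endpoint differences", {
  lm <- regular_landmarks(n_cycles = 5, inhale_ms = 1800, exhale_ms = 2200)
  t <- seq(0, 19999, by = 1000 / 60)
  ph <- compute_phase(lm, t)
  vals <- 0.5 * sin(ph$phase_deg * pi / 180)
  vals[is.na(vals)] <- 0
  valid <- rep(TRUE, length(vals))
  out <- derivative_by_bin(vals, valid, ph)

  # closed form: summed change in bin k ~ A (sin(right edge) - sin(left edge))
  edges <- seq(0, 360, by = 20) * pi / 180
  oracle <- 0.5 * (sin(edges[-1]) - sin(edges[-19]))
  # discretization: one sample of change can land in the neighbouring bin
  expect_lt(max(abs(out$derivative_z - oracle)), 0.025)

  # telescoping identity per cycle
  pair_ok <- which(ph$valid[-1] & ph$valid[-length(t)] &
                     ph$cycle_id[-1] == ph$cycle_id[-length(t)]) + 1L
  for (cyc in 2:4) {
    in_cyc <- pair_ok[ph$cycle_id[pair_ok] == cyc]
    d <- tibble::tibble(bin = assign_bins(ph$phase_deg[in_cyc]),
                        dd = vals[in_cyc] - vals[in_cyc - 1L])
    total <- sum(d$dd)
    expect_equal(total, vals[max(in_cyc)] - vals[min(in_cyc) - 1L],
                 tolerance = 1e-12)
  }

  # constant pupil: all-zero derivatives
  out0 <- derivative_by_bin(rep(1, length(t)), valid, ph)
  expect_true(all(out0$derivative_z[out0$n_cycles > 0] == 0))
})

test_that("the sign-flip max-t p-values match the exhaustive oracle", {
  obs <- list(c(0.9, 1.3, 0.2, 0.8), c(-0.1, 0.4, -0.6, 0.3))
  oracle <- exhaustive_max_t(obs)
  mc <- signflip_max_t_test(obs, n_permutations = 10000, seed = 42)
  expect_equal(mc$t_observed, oracle$t_obs, tolerance = 1e-12)
  for (b in 1:2) {
    se <- sqrt(oracle$p[b] * (1 - oracle$p[b]) / 10000)
    expect_lt(abs(mc$p_fwe[b] - oracle$p[b]), 3 * se + 1e-12)
  }
})

test_that("degenerate observations give the documented t conventions", {
  allzero <- signflip_max_t_test(rep(list(rep(0, 5)), 3),
                                 n_permutations = 200, seed = 1)
  expect_true(all(allzero$t_observed == 0))
  expect_true(all(allzero$p_fwe == 1))
  # zero variance, nonzero mean: t is infinite and sorts above all finite
  inf_bin <- signflip_max_t_test(list(c(2, 2, 2), rnorm(5)),
                                 n_permutations = 200, seed = 1)
  expect_identical(inf_bin$t_observed[1], Inf)
})

test_that("permutation p-values are reproducible and internally coherent", {
  obs <- withr::with_seed(7, lapply(1:6, function(i) rnorm(30, mean = 0.2)))
  a <- signflip_max_t_test(obs, n_permutations = 2000, seed = 99)
  b <- signflip_max_t_test(obs, n_permutations = 2000, seed = 99)
  expect_identical(a$p_fwe, b$p_fwe)
  # relabelling bins permutes the observed statistics exactly and the
  # p-values up to Monte-Carlo error in the shared null
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  c_ <- signflip_max_t_test(obs[perm], n_permutations = 2000, seed = 99)
  expect_equal(sort(c_$p_fwe), sort(a$p_fwe), tolerance = 0.05)
  expect_equal(c_$t_observed, a$t_observed[perm], tolerance = 1e-12)
  # family-wise correction can only increase p
  expect_true(all(a$p_fwe >= a$p_uncorrected - 1e-12))
})

test_that("weighted circular means point where they should", {
  centers <- bin_centers()
  w <- rep(0, 18); w[10] <- 0.4        # single weight at 190 degrees
  expect_equal(circular_mean_direction(w, centers), 190)

  w2 <- cos((centers - 200) * pi / 180)
  expect_equal(circular_mean_direction(w2, centers), 200, tolerance = 1e-6)

  expect_warning(d <- circular_mean_direction(rep(1, 18), centers),
                 "zero resultant")
  expect_true(is.na(d))
  expect_error(circular_mean_direction(rep(0, 18), centers), "nonzero")

  # rotation equivariance
  for (delta in c(30, 123.4, 270)) {
    expect_equal(circular_mean_direction(w2, (centers + delta) %% 360),
                 (200 + delta) %% 360, tolerance = 1e-6)
  }
})

test_that("the Rayleigh test behaves at both extremes and under effects", {
  grid <- rayleigh_test(bin_centers())   # perfectly uniform grid
  expect_lt(grid$R, 1e-12)
  expect_equal(grid$p, 1, tolerance = 1e-6)

  conc <- rayleigh_test(rep(220, 20))
  expect_equal(conc$R, 1)
  expect_lt(conc$p, 1e-6)

  expect_error(rayleigh_test(c(10, 20)), "at least 3")

  # von Mises kappa = 2, n = 50: significant in >= 99/100 replicates
  hits <- withr::with_seed(31, vapply(1:100, function(i) {
    u <- runif(600, -pi, pi)
    keep <- runif(600) < exp(2 * (cos(u) - 1))   # rejection sampler
    th <- u[keep][1:50] * 180 / pi
    rayleigh_test(th)$p < 0.001
  }, logical(1)))
  expect_gte(mean(hits), 0.99)
})

test_that("proportion toward exhalation uses the [180, 360) sector", {
  expect_equal(proportion_toward_exhalation(c(190, 200, 10)), 2 / 3)
  expect_equal(proportion_toward_exhalation(rep(90, 5)), 0)
  expect_equal(proportion_toward_exhalation(c(180, 359.9)), 1)
})

test_that("time-binned means are exact on simple traces", {
  n <- 300 * 60
  lin <- pupil_trace(seq(5, 4, length.out = n), rate = 60, unit = "mm")
  out <- time_bin_means(lin)
  expect_true(all(diff(out$mean_pupil) < 0))
  expect_true(all(out$n_observations == n / 18))

  const <- pupil_trace(rep(4.5, n), rate = 60, unit = "mm")
  expect_true(all(time_bin_means(const)$mean_pupil == 4.5))
})
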