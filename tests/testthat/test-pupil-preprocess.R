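cfg <- cleaning_config()

test_that("valid stretches shorter than 250 ms are invalidated", {
  # 14 samples at 60 Hz = 233 ms < 250 ms -> gone
  tr <- gapped_trace(smooth_pupil(300), list(c(1, 100), c(115, 186)))
  expect_equal(sum(tr$valid), 14L)
  out <- mark_unreliable_valid_stretches(tr, cfg, "initial")
  expect_equal(sum(out$valid), 0L)

  # 15 samples = 250 ms, not shorter -> kept
  tr2 <- gapped_trace(smooth_pupil(300), list(c(1, 100), c(116, 185)))
  out2 <- mark_unreliable_valid_stretches(tr2, cfg, "initial")
  expect_equal(sum(out2$valid), 15L)
})

test_that("valid islands inside long invalid context are invalidated", {
  # 20 valid samples (333 ms) flanked by 150-sample (2.5 s) invalid runs
  vals <- smooth_pupil(500)
  tr <- gapped_trace(vals, list(c(21, 150), c(191, 150)))
  out <- mark_unreliable_valid_stretches(tr, cfg, "initial")
  expect_false(any(out$valid[171:190]))
  # flanked by only 1.5 s (90 samples): island survives the initial stage
  tr2 <- gapped_trace(vals, list(c(81, 90), c(191, 90)))
  out2 <- mark_unreliable_valid_stretches(tr2, cfg, "initial")
  expect_true(all(out2$valid[171:190]))
})

test_that("post-interpolation stage adds the 1000 ms / 5 s island rule", {
  # 50 valid samples (833 ms) flanked by 350-sample (5.8 s) invalid runs:
  # survives the initial stage, dies after interpolation
  vals <- smooth_pupil(800)
  tr <- gapped_trace(vals, list(c(51, 350), c(451, 350)))
  island <- 401:450
  init <- mark_unreliable_valid_stretches(tr, cfg, "initial")
  expect_true(all(init$valid[island]))
  post <- mark_unreliable_valid_stretches(tr, cfg, "post_interpolation")
  expect_false(any(post$valid[island]))
})

test_that("fully valid traces pass the validity rules unchanged", {
  tr <- pupil_trace(smooth_pupil(600), rate = 60)
  out <- mark_unreliable_valid_stretches(tr, cfg, "post_interpolation")
  expect_identical(out$valid, tr$valid)
  expect_identical(out$values, tr$values)
})

test_that("invalid stretches longer than 500 ms are removed, shorter kept", {
  vals <- smooth_pupil(600)
  tr <- gapped_trace(vals, list(c(101, 36), c(301, 12)))  # 600 ms and 200 ms
  out <- remove_long_invalid(tr, cfg)
  expect_true(all(out$removed[101:136]))
  expect_false(any(out$removed[301:312]))
  # 30 samples = exactly 500 ms is not "more than" 500 ms
  tr2 <- gapped_trace(vals, list(c(101, 30)))
  expect_false(any(remove_long_invalid(tr2, cfg)$removed))
  # all-valid trace: nothing removed
  expect_false(any(remove_long_invalid(pupil_trace(vals, rate = 60), cfg)$removed))
})

test_that("spline interpolation reproduces polynomials through gaps", {
  t <- seq_len(60)
  vals <- 0.02 * (t - 30)^2 + 500          # exact parabola
  tr <- gapped_trace(vals, list(c(25, 6)))
  truth <- tr$values
  out <- interpolate_gaps(tr, cfg, "first_pass")
  expect_true(all(out$valid[25:30]))
  expect_lt(max(abs(out$values[25:30] - truth[25:30]) / abs(truth[25:30])),
            1e-6)
})

test_that("the range guard rejects spline overshoot and falls back to linear", {
  # alternating +/-50 anchors make every buffered spline (2, 3, 4 frames)
  # overshoot the 100-unit anchor range by far more than 30% (verified by
  # direct recomputation of each candidate spline), forcing the linear path
  n <- 40
  vals <- rep(100, n)
  idx <- c(11:17, 22:28)
  vals[idx] <- 100 + 50 * (-1)^idx
  for (b in 2:4) {
    anch <- c((18 - b - 3):(18 - b - 1), (21 + b + 1):(21 + b + 3))
    fill <- splinefun(anch, vals[anch], method = "fmm")((18 - b):(21 + b))
    expect_gt(diff(range(fill)), diff(range(vals[anch])) * 1.3)
  }
  tr <- gapped_trace(vals, list(c(18, 4)))   # gap 18..21
  out <- interpolate_gaps(tr, cfg, "first_pass")
  expect_true(all(out$valid[16:23]))
  # linear interpolation between the inner buffer frames (17, 50) -> (22, 150)
  expect_equal(out$values[18:21], c(70, 90, 110, 130))
  # buffer frames keep their recorded values on the linear path
  expect_equal(out$values[c(16, 17, 22, 23)], vals[c(16, 17, 22, 23)])
})

test_that("gaps at the trace edge or without anchors stay invalid", {
  vals <- smooth_pupil(100)
  tr <- gapped_trace(vals, list(c(1, 6)))
  out <- interpolate_gaps(tr, cfg, "first_pass")
  expect_false(any(out$valid[1:6]))
  # interior gap whose anchors are farther than 2 s away is unfillable
  tr2 <- gapped_trace(smooth_pupil(500), list(c(41, 140), c(185, 2), c(191, 140)))
  out2 <- interpolate_gaps(remove_long_invalid(tr2, cfg), cfg, "first_pass")
  expect_false(any(out2$valid[185:186]))
})

test_that("rapid-change detection flags steps and nothing else", {
  vals <- smooth_pupil(1200)              # smooth 0.25 Hz sine
  tr <- pupil_trace(vals, rate = 60)
  expect_equal(sum(detect_rapid_changes(tr, cfg)), 0L)

  spiked <- vals
  spiked[600] <- spiked[600] + 10 * 50    # 10x signal amplitude step
  tr2 <- pupil_trace(spiked, rate = 60)
  # brute-force threshold on the fixture
  d <- diff(spiked)
  thr <- cfg$speed_mad_multiplier * mad(d)
  expect_true(any(abs(d) > thr))
  mask <- detect_rapid_changes(tr2, cfg)
  expect_true(all(mask[(600 - 1):(600 + 1)]))
  expect_lt(sum(mask), 12L)               # localized around the step

  const <- pupil_trace(rep(5, 100), rate = 60)
  expect_equal(sum(detect_rapid_changes(const, cfg)), 0L)
})

test_that("outlier masking follows the mean +/- 3 SD rule", {
  vals <- c(rep(4, 999), 10)
  tr <- pupil_trace(vals, rate = 60)
  out <- mask_outliers(tr, cfg)
  # direct computation: 10 is far outside mean + 3 sd
  expect_gt(10, mean(vals) + 3 * sd(vals))
  expect_false(out$valid[1000])
  expect_true(all(out$valid[1:999]))

  const <- pupil_trace(rep(4, 100), rate = 60)
  expect_identical(mask_outliers(const, cfg)$valid, const$valid)
})

test_that("a Gaussian trace loses about 0.27% of samples to the 3 SD rule", {
  tr <- pupil_trace(withr::with_seed(99, rnorm(1e5)), rate = 60)
  out <- mask_outliers(tr, cfg)
  frac <- mean(!out$valid)
  # 2*pnorm(-3) = 0.0027; MC tolerance ~4 SE
  se <- sqrt(0.0027 * 0.9973 / 1e5)
  expect_lt(abs(frac - 0.0027), 4 * se + 1e-4)
})

test_that("session exclusion requires both eyes above 30% invalid", {
  mk <- function(frac) {
    v <- rep(TRUE, 1000); v[seq_len(round(frac * 1000))] <- FALSE
    pupil_trace(smooth_pupil(1000), valid = v, rate = 60)
  }
  expect_true(session_excluded(mk(0.31), mk(0.32), cfg))
  expect_false(session_excluded(mk(0.31), mk(0.05), cfg))
  expect_false(session_excluded(mk(0.30), mk(0.30), cfg))  # not "more than"
  expect_equal(validity_fraction(mk(0)), 0)
})

test_that("eye averaging uses the valid eye when only one is valid", {
  l <- pupil_trace(c(2, 4, 7), valid = c(TRUE, TRUE, FALSE), rate = 60)
  r <- pupil_trace(c(4, 6, 5), valid = c(TRUE, FALSE, FALSE), rate = 60)
  out <- combine_eyes(l, r)
  expect_equal(out$values[1], 3)
  expect_equal(out$values[2], 4)      # left only
  expect_false(out$valid[3])
  strict <- combine_eyes(l, r, mode = "both")
  expect_false(strict$valid[2])
  expect_error(combine_eyes(l, pupil_trace(1:2, rate = 60)), "length")
})

test_that("z-scoring is exact, affine-invariant, and pools sessions", {
  tr <- pupil_trace(c(1, 2, 3), rate = 60)
  z <- zscore_trace(tr)
  expect_equal(z$values, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)

  base <- pupil_trace(smooth_pupil(500), rate = 60)
  aff <- pupil_trace(3.2 * base$values + 17, rate = 60)
  expect_equal(zscore_trace(base)$values, zscore_trace(aff)$values,
               tolerance = 1e-9)

  s1 <- pupil_trace(rep(c(1, 3), 50), rate = 60)
  s2 <- pupil_trace(rep(c(11, 13), 50), rate = 60)
  zz <- zscore_trace(list(s1, s2))
  pooled <- c(zz[[1]]$values, zz[[2]]$values)
  expect_equal(mean(pooled), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(pooled^2)), 1, tolerance = 1e-9)
  expect_error(zscore_trace(pupil_trace(rep(4, 10), rate = 60)), "variance")
})

test_that("nearest-neighbour downsampling is exact where it should be", {
  const <- pupil_trace(rep(4.2, 1000), rate = 1000)
  down <- resample_trace(const, 60)
  expect_true(all(down$values == 4.2))
  expect_equal(down$rate, 60)

  t <- (0:9999) / 1000
  sine <- pupil_trace(sin(2 * pi * t), rate = 1000)
  down2 <- resample_trace(sine, 100)
  t100 <- (seq_len(length(down2)) - 1) / 100
  # nearest-neighbour bound: |error| <= amplitude * 2*pi*f * half source step
  expect_lte(max(abs(down2$values - sin(2 * pi * t100))),
             2 * pi * 1 * 0.5 / 1000 + 1e-12)

  same <- resample_trace(sine, 1000)
  expect_identical(same$values, sine$values)
  expect_error(resample_trace(sine, 2000), "upsampling")
})

test_that("cleaning never alters samples that stay valid outside buffers", {
  vals <- smooth_pupil(1200)
  tr <- gapped_trace(vals, list(c(200, 10), c(500, 40), c(900, 5)))
  out <- preprocess_pupil(tr, cfg)
  buffered <- rep(FALSE, 1200)
  for (g in list(c(200, 10), c(500, 40), c(900, 5))) {
    buffered[max(1, g[1] - 4):min(1200, g[1] + g[2] - 1 + 4)] <- TRUE
  }
  keep <- tr$valid & out$valid & !buffered & !out$interpolated
  expect_gt(sum(keep), 1000)
  expect_identical(out$values[keep], vals[keep])
})

test_that("the invalid fraction is monotone across marking and filling", {
  tr <- gapped_trace(smooth_pupil(2000), list(c(100, 20), c(700, 12), c(1500, 40)))
  f0 <- mean(!tr$valid)
  m <- mark_unreliable_valid_stretches(tr, cfg, "initial")
  f1 <- mean(!m$valid)
  r <- remove_long_invalid(m, cfg)
  f2 <- mean(!r$valid)
  i <- interpolate_gaps(r, cfg, "first_pass")
  f3 <- mean(!i$valid)
  expect_gte(f1, f0)
  expect_gte(f2, f1)
  expect_lte(f3, f2)
})

test_that("the full pipeline is idempotent on its own output", {
  tr <- gapped_trace(smooth_pupil(3000), list(c(100, 20), c(1500, 40)))
  once <- preprocess_pupil(tr, cfg)
  twice <- preprocess_pupil(once, cfg)
  expect_identical(once$values, twice$values)
  expect_identical(once$valid, twice$valid)
  expect_identical(once$removed, twice$removed)
  # finalized traces are exactly {valid, removed}
  expect_true(all(xor(once$valid, once$removed)))
})

test_that("interpolation error on blink-like gaps is under 5% of amplitude", {
  vals <- smooth_pupil(3000, amp = 50)
  gaps <- list(c(300, 12), c(800, 20), c(1400, 24), c(2100, 8), c(2600, 18))
  tr <- gapped_trace(vals, gaps)
  out <- preprocess_pupil(tr, cfg)
  filled <- out$interpolated & out$valid
  expect_gt(sum(filled), 50)
  rmse <- sqrt(mean((out$values[filled] - vals[filled])^2))
  expect_lt(rmse, 0.05 * 50)
})
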