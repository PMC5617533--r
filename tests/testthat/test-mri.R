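test_that("SPGR signal equation behaves at its limits", {
  expect_equal(spgr_signal(750, t1_ms = 10, tr_ms = 1e5, alpha_deg = 90),
               750, tolerance = 1e-12)
  expect_equal(spgr_signal(1000, 1000, 3.5, 0), 0)
  # frozen closed-form value, m0 = 1000, T1 = 1000 ms, TR = 3.5 ms, 15 deg
  e1 <- exp(-3.5 / 1000)
  expect_equal(spgr_signal(1000, 1000, 3.5, 15),
               1000 * sin(15 * pi / 180) * (1 - e1) /
                 (1 - e1 * cos(15 * pi / 180)))
  expect_equal(spgr_signal(1000, 1000, 3.5, 15), 24.14706, tolerance = 1e-6)
  expect_error(spgr_signal(1000, -5, 3.5, 15), "t1_ms")
})

test_that("VFA regression recovers T1 and M0 from noiseless signals", {
  ang <- c(4, 8, 15, 25)
  s <- spgr_signal(800, 1000, 3.5, ang)
  fit <- fit_t10_vfa(s, ang, 3.5)
  expect_lt(abs(fit$t10_ms - 1000) / 1000, 0.001)
  expect_lt(abs(fit$m0 - 800) / 800, 0.001)
  expect_error(fit_t10_vfa(s[1], ang[1], 3.5), "two distinct")
})

test_that("VFA T1 estimate has small median bias at 1% noise", {
  ang <- c(4, 8, 15, 25)
  s0 <- spgr_signal(800, 1000, 3.5, ang)
  set.seed(99)
  est <- replicate(1000, {
    s <- s0 * (1 + rnorm(4, sd = 0.01))
    tryCatch(fit_t10_vfa(s, ang, 3.5)$t10_ms, error = function(e) NA_real_)
  })
  expect_lt(abs(median(est, na.rm = TRUE) - 1000) / 1000, 0.02)
})

test_that("signal-to-concentration inverts the forward model", {
  times <- default_times(40)
  aif <- aif_population(times)
  ct <- kety_forward(0.3, 0.35, 0.04, aif)
  t10 <- 1200; tr <- 3.5; alpha <- 15; r1 <- 3.6
  r1_t <- 1000 / t10 + r1 * ct
  sig <- spgr_signal(900, 1000 / r1_t, tr, alpha)
  conc <- signal_to_concentration(sig, t10, tr, alpha, r1)
  expect_length(attr(conc, "flagged"), 0)
  expect_equal(as.numeric(conc), as.numeric(ct), tolerance = 1e-6)
  # constant baseline signal maps to zero concentration
  base <- rep(sig[1], 40)
  cb <- signal_to_concentration(base, t10, tr, alpha, r1)
  expect_true(all(cb == 0))
  # doubling relaxivity halves the recovered concentration
  conc2 <- signal_to_concentration(sig, t10, tr, alpha, r1 = 2 * r1)
  expect_equal(as.numeric(conc2), as.numeric(ct) / 2, tolerance = 1e-6)
})

test_that("Kety forward model honours its degenerate cases", {
  times <- default_times(30)
  aif <- aif_population(times)
  expect_true(all(kety_forward(0, 0.3, 0, aif) == 0))
  expect_equal(kety_forward(0, 0.3, 1, aif), aif$cp_mM)
})

test_that("piecewise-linear convolution matches the step-AIF closed form", {
  times <- default_times(80)              # 80 frames at 3.3 s
  cc <- 5
  aif <- aif_curve(times, rep(cc, 80))    # step of height c from t = 0
  kt <- 0.25; ve <- 0.3; vp <- 0.02; kep <- kt / ve
  num <- kety_forward(kt, ve, vp, aif)
  tmin <- times / 60
  ana <- vp * cc + kt * cc / kep * (1 - exp(-kep * tmin))
  expect_lt(max(abs(num - ana)), 1e-8)
})

test_that("extended-Kety fitting recovers noiseless ground truth", {
  times <- default_times(80)
  aif <- aif_population(times)
  ct <- kety_forward(0.25, 0.3, 0.02, aif)
  f <- fit_extended_kety(ct, aif)
  expect_lt(abs(f$ktrans - 0.25) / 0.25, 0.01)
  expect_lt(abs(f$ve - 0.3) / 0.3, 0.01)
  expect_lt(abs(f$vp - 0.02) / 0.02, 0.01)
  expect_equal(f$kep, f$ktrans / f$ve, tolerance = 1e-9)
  expect_false(f$flagged)
})

test_that("an all-zero tissue curve is flagged with parameters at bounds", {
  times <- default_times(30)
  aif <- aif_population(times)
  f <- fit_extended_kety(rep(0, 30), aif)
  expect_equal(f$ktrans, 0)
  expect_equal(f$vp, 0)
  expect_true(f$flagged)
})

test_that("Ktrans is recovered within 10% median error at SNR 20", {
  times <- default_times(80)
  aif <- aif_population(times)
  set.seed(123)
  nvox <- 150
  err <- vapply(seq_len(nvox), function(i) {
    kt <- runif(1, 0.1, 1); ve <- runif(1, 0.15, 0.6)
    vp <- runif(1, 0.01, 0.08)
    ct <- kety_forward(kt, ve, vp, aif)
    noisy <- ct + rnorm(80, sd = max(ct) / 20)
    f <- fit_extended_kety(noisy, aif)
    abs(f$ktrans - kt) / kt
  }, numeric(1))
  expect_lt(median(err), 0.10)
})

test_that("ADC map follows the log-ratio closed form and flags bad voxels", {
  expect_equal(as.numeric(compute_adc(1000, 1000, 800)), 0)
  expect_equal(as.numeric(compute_adc(1000, 1000 * exp(-0.8), 800)), 1.0,
               tolerance = 1e-12)
  adc <- compute_adc(c(1000, 1000, -5), c(1100, 500, 10), 800)
  expect_lt(adc[1], 0)
  expect_identical(attr(adc, "flagged_negative"), 1L)
  expect_true(is.na(adc[3]))
  expect_identical(attr(adc, "flagged_signal"), 3L)
})

test_that("ROI summaries exclude flagged voxels", {
  m <- array(2, c(2, 2, 1))
  msk <- array(TRUE, c(2, 2, 1))
  expect_equal(roi_summarize(m, msk), 2)
  m2 <- array(c(1, 2, 3, NA), c(2, 2, 1))
  expect_equal(roi_summarize(m2, msk), 2)
  m3 <- array(c(1, NA, 3, NA), c(2, 2, 1))
  expect_equal(roi_summarize(m3, msk), 2)
  expect_equal(roi_summarize(m2, msk, statistic = median), 2)
  expect_error(roi_summarize(m, array(FALSE, c(2, 2, 1))), "empty")
})

test_that("the full DCE chain round-trips through the estimators", {
  times <- default_times(80)
  aif <- aif_population(times)
  d <- c(3, 3, 1)
  set.seed(8)
  kt <- array(runif(prod(d), 0.05, 1), d)
  ve <- array(runif(prod(d), 0.1, 0.6), d)
  vp <- array(runif(prod(d), 0.005, 0.1), d)
  t10 <- array(runif(prod(d), 700, 1500), d)
  ser <- generate_dce_series(kt, ve, vp, aif, t10)
  maps <- fit_kety_map(ser$dynamic, aif, array(TRUE, d), vfa = ser$vfa)
  expect_true(all(abs(maps$ktrans - kt) / kt < 0.01))
  expect_true(all(abs(maps$ve - ve) / ve < 0.01))
  expect_true(all(abs(maps$vp - vp) / vp < 0.01))
  expect_true(all(abs(maps$kep - kt / ve) / (kt / ve) < 0.01))
  expect_false(any(maps$flagged))
})
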