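mk_lfp <- function(mat, fs = 2500, layers = rep("IV", nrow(mat))) {
  structure(list(samples = mat, fs = fs, band = "LFP",
                 channels = data.frame(index = seq_len(nrow(mat)),
                                       layer = layers, in_cortex = TRUE)),
            class = "band_signal")
}

test_that("layer mean is the arithmetic mean of member channels", {
  x <- rnorm(100)
  expect_equal(layer_mean_lfp(mk_lfp(matrix(x, 1)), "IV"), x)
  m <- rbind(x, -x)
  expect_equal(layer_mean_lfp(mk_lfp(m), "IV"), rep(0, 100))
  expect_error(layer_mean_lfp(mk_lfp(matrix(x, 1)), "Vb"), "unknown")
})

test_that("onset latency crosses at the planted onset and respects the 3-sigma rule", {
  fs <- 2500
  # flat trace: no onset
  flat <- rep(0, 3 * fs)
  expect_true(is.na(response_onset_latency(flat, fs, 2, baseline_window = 1)))
  # planted template with onset 8 ms after the stimulus instant
  tt <- seq(0, 0.4, by = 1 / fs)
  tr <- c(rep(0, 2 * fs), lfp_template(tt, 200, rol_shift_ms = 3), rep(0, fs))
  rol <- response_onset_latency(tr, fs, 2, baseline_window = 1, smooth_ms = 0)
  expect_lt(abs(rol - 8), 1000 / fs + 1e-9)  # within one sample of 5 ms pulse + 3 ms shift
  # threshold formula: baseline derivative mean 0, sd 2 uV/ms -> thr 6
  set.seed(1)
  dx <- rnorm(5000, 0, 2)
  thr <- mean(dx) + 3 * sd(dx)
  expect_lt(abs(thr - 6), 0.3)
})

test_that("peak amplitude is the onset-to-peak drop and scales linearly", {
  fs <- 2500
  tt <- seq(0, 0.4, by = 1 / fs)
  tr <- c(rep(0, fs), lfp_template(tt, 120))
  rol <- response_onset_latency(tr, fs, 1, baseline_window = 0.5, smooth_ms = 0)
  pk <- response_peak_amplitude(tr, fs, 1, rol)
  expect_lt(abs(pk$rp - (-120)), 1)
  # the onset-instant voltage sits a few uV into the steep initial slope
  expect_lt(abs(pk$rpa - 120), 5)
  expect_lt(abs(pk$peak_ms - 25), 1)
  # trace(ROL)=0, RP=-120 -> RPA = 120 (formula evaluation)
  expect_equal(abs(0 - (-120)), 120)
  # doubling the trace doubles RPA, leaves ROL unchanged
  tr2 <- 2 * tr
  rol2 <- response_onset_latency(tr2, fs, 1, baseline_window = 0.5, smooth_ms = 0)
  expect_equal(rol2, rol)
  expect_equal(response_peak_amplitude(tr2, fs, 1, rol2)$rpa, 2 * pk$rpa,
               tolerance = 1e-9)
  # constant trace: RPA 0
  cst <- rep(5, 2 * fs)
  expect_equal(response_peak_amplitude(cst, fs, 0.4, 2)$rpa, 0)
  expect_true(is.na(response_peak_amplitude(cst, fs, 0.4, NA_real_)$rpa))
})

test_that("positive rebound is the post-peak maximum, absent when non-positive", {
  fs <- 2500
  tt <- seq(0, 0.4, by = 1 / fs)
  tr <- c(rep(0, fs), lfp_template(tt, 100))
  pr <- positive_rebound(tr, fs, 1, 25)
  expect_gt(pr, 0)
  expect_lt(abs(pr - max(tr)), 1e-9)
  expect_true(is.na(positive_rebound(-abs(rnorm(5000)), fs, 0.5, 25)))
  expect_true(is.na(positive_rebound(seq(0, -100, length.out = 5000), fs, 0.5, 25)))
})

test_that("time-normalized LFP matches the closed-form triangle value", {
  fs <- 1000
  d <- 80; half <- 50  # 50 ms down, 50 ms up -> RD 100 ms
  tr <- c(rep(0, fs), seq(0, -d, length.out = half + 1)[-1],
          seq(-d, 0, length.out = half + 1)[-1], rep(0, fs))
  rol <- response_onset_latency(tr, fs, 1, baseline_window = 0.5, smooth_ms = 0)
  pk <- response_peak_amplitude(tr, fs, 1, rol)
  tl <- time_normalized_lfp(tr, fs, 1, rol, pk$peak_ms)
  expect_lt(abs(tl$tlfp - d / 2), d * 0.03)
  # RD shortened by ~one sample at each end (onset voltage is one step down)
  expect_lt(abs(tl$rd_ms - 100), 6)
  expect_false(tl$capped)
  # zero trace after onset -> 0; scaling doubles tLFP
  tl2 <- time_normalized_lfp(2 * tr, fs, 1, rol, pk$peak_ms)
  expect_equal(tl2$tlfp, 2 * tl$tlfp, tolerance = 1e-9)
  # never-returning trace is capped
  mono <- c(rep(0, fs), seq(0, -d, length.out = fs))
  tlc <- time_normalized_lfp(mono, fs, 1, 1, 600)
  expect_true(tlc$capped)
  expect_equal(tlc$rd_ms, 300, tolerance = 2)
})

test_that("evoked MUA features follow the first-spike definition", {
  times <- c(0.5, 1.012, 1.018, 1.026, 1.4)
  mf <- mua_features(times, onset = 1)
  expect_equal(mf$latency_ms, 12)
  expect_equal(mf$duration_ms, 14)
  expect_equal(mf$rate_hz, 3 / 0.014, tolerance = 1e-9)
  # no evoked spikes -> missing row
  expect_true(is.na(mua_features(c(0.1, 0.2), onset = 1)$latency_ms))
  # single spike: zero duration, missing rate
  m1 <- mua_features(c(1.020), onset = 1)
  expect_equal(m1$duration_ms, 0)
  expect_true(is.na(m1$rate_hz))
})

test_that("features are invariant under time translation", {
  fs <- 2500
  tt <- seq(0, 0.4, by = 1 / fs)
  base <- c(rep(0, fs), lfp_template(tt, 150), rep(0, fs))
  tr_shift <- c(rep(0, fs), base)  # whole recording shifted by 1 s
  r1 <- response_onset_latency(base, fs, 1, baseline_window = 0.5, smooth_ms = 0)
  r2 <- response_onset_latency(tr_shift, fs, 2, baseline_window = 0.5, smooth_ms = 0)
  expect_equal(r1, r2)
  p1 <- response_peak_amplitude(base, fs, 1, r1)
  p2 <- response_peak_amplitude(tr_shift, fs, 2, r2)
  expect_equal(p1$rpa, p2$rpa)
  mf1 <- mua_features(c(1.01, 1.02), 1)
  mf2 <- mua_features(c(6.01, 6.02), 6)
  expect_equal(mf1, mf2)
})

test_that("the feature table recovers every planted ordering", {
  f <- fix_small()
  lab <- label_stimuli(compute_ifr(f$raster), f$g$stimuli)
  fx <- extract_features(f$lfp, f$raster, f$g$stimuli, states = lab$state,
                         baseline_window = 1)
  iv <- fx$lfp[fx$lfp$layer == "IV", ]
  m <- tapply(iv$RPA, iv$amp_class, mean, na.rm = TRUE)
  expect_gt(m[["large"]], m[["medium"]])
  expect_gt(m[["medium"]], m[["small"]])
  ms <- tapply(iv$RPA, iv$state, mean, na.rm = TRUE)
  expect_gt(ms[["DOWN"]], ms[["UP"]])
  rolm <- tapply(iv$ROL, iv$amp_class, mean, na.rm = TRUE)
  expect_gt(rolm[["small"]], rolm[["large"]])
  mu <- fx$mua[fx$mua$layer == "IV", ]
  lat <- tapply(mu$latency, mu$state, mean, na.rm = TRUE)
  expect_gt(lat[["DOWN"]], lat[["UP"]])
})
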