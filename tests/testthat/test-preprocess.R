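make_rec <- function(x, fs = 10000) {
  list(samples = matrix(x, nrow = 1), fs = fs,
       channels = data.frame(index = 1L, layer = "IV", in_cortex = TRUE))
}

test_that("band filters pass and reject where designed", {
  fs <- 10000
  t <- (0:(6 * fs - 1)) / fs
  core <- (fs):(5 * fs)
  s1k <- sin(2 * pi * 1000 * t)
  lfp <- bandpass(make_rec(s1k), "LFP")
  expect_lt(sd(lfp$samples[1, core]) / sd(s1k), 0.05)
  spk <- bandpass(make_rec(s1k), "SPIKE")
  expect_gt(sd(spk$samples[1, core]) / sd(s1k), 0.95)  # inside 0.1 dB ripple (x2 for two passes)
  s10 <- sin(2 * pi * 10 * t)
  expect_gt(sd(bandpass(make_rec(s10), "LFP")$samples[1, core]) / sd(s10), 0.95)
  expect_lt(sd(bandpass(make_rec(s10), "SPIKE")$samples[1, core]) / sd(s10), 0.01)
  z <- bandpass(make_rec(numeric(fs)), "LFP")
  expect_true(all(z$samples == 0))
})

test_that("Nyquist violations and downsampling contract are enforced", {
  expect_error(bandpass(make_rec(rnorm(1000), fs = 5000), "SPIKE"), "Nyquist")
  expect_error(bandpass(make_rec(rnorm(1000)), "SPIKE", downsample_to = 1000),
               "LFP")
  expect_error(bandpass(make_rec(rnorm(1000)), "LFP", downsample_to = 3000),
               "divide")
  d <- bandpass(make_rec(rnorm(20000)), "LFP", downsample_to = 2500)
  expect_equal(d$fs, 2500)
  expect_equal(ncol(d$samples), 5000)
})

test_that("mid-band signals are near-idempotent under double filtering", {
  fs <- 10000
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 80 * t)
  l1 <- bandpass(make_rec(x), "LFP")
  l2 <- bandpass(list(samples = l1$samples, fs = fs, channels = l1$channels), "LFP")
  core <- fs:(3 * fs)
  expect_lt(abs(sd(l2$samples[1, core]) - sd(l1$samples[1, core])) /
              sd(l1$samples[1, core]), 0.01)
})

test_that("spike detection threshold follows the 3-sigma rule", {
  # sigma 10 -> threshold 30
  set.seed(7)
  x <- rnorm(100000, sd = 10)
  sig <- structure(list(samples = matrix(x, 1), fs = 10000, band = "SPIKE",
                        channels = make_rec(0)$channels), class = "band_signal")
  r <- detect_spikes(sig)
  expect_equal(r$threshold, 3 * r$sigma)
  expect_equal(r$sigma, median(abs(x)) / 0.6745)
  expect_lt(abs(r$sigma - 10), 0.2)
  # zero signal: no division error, no spikes
  z <- detect_spikes(structure(list(samples = matrix(0, 1, 1000), fs = 10000,
                                    band = "SPIKE", channels = sig$channels),
                               class = "band_signal"))
  expect_equal(z$sigma, 0)
  expect_equal(lengths(z$times), 0L)
})

test_that("injected spikes are recovered at their times with no extras", {
  fs <- 10000
  set.seed(8)
  # bounded narrowband background + small white noise, as the detector assumes
  t <- (0:(10 * fs - 1)) / fs
  x <- 10 * sin(2 * pi * 450 * t) + rnorm(length(t), sd = 1)
  inj <- c(1.0, 2.5, 4.0, 6.2, 8.8)
  shape <- whiskdecode:::spike_waveform(fs, 1)
  x <- whiskdecode:::add_waveforms(x, shape, round(inj * fs) + 1L, rep(80, 5))
  r <- detect_spikes(bandpass(make_rec(x), "SPIKE"))
  det <- r$times[[1]]
  expect_equal(length(det), 5L)
  expect_true(all(vapply(inj, function(s) min(abs(det - s)) < 5e-4, TRUE)))
})

test_that("detector matches the brute-force scan on arbitrary traces", {
  fs <- 2000
  set.seed(9)
  for (rep in 1:5) {
    x <- rnorm(4000, sd = 5)
    x[sample(4000, 8)] <- x[sample(4000, 8)] + sample(c(-60, 60), 8, TRUE)
    sig <- structure(list(samples = matrix(x, 1), fs = fs, band = "SPIKE",
                          channels = make_rec(0)$channels), class = "band_signal")
    expect_equal(detect_spikes(sig)$times[[1]], oracle_detect(x, fs))
  }
})

test_that("MUA grouping follows the strict 20 ms gap rule", {
  mk_raster <- function(times) {
    structure(list(times = list(times), sigma = 1, threshold = 3,
                   channels = data.frame(index = 1L, layer = "IV",
                                         in_cortex = TRUE),
                   span = c(0, 1)), class = "spike_raster")
  }
  ev <- group_mua(mk_raster(c(0, 0.015, 0.030)))
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$t1, ev$t2, ev$n_spikes), c(0, 0.030, 3))
  ev2 <- group_mua(mk_raster(c(0, 0.025)))
  expect_equal(nrow(ev2), 2L)
  # tie at exactly 20 ms splits
  ev3 <- group_mua(mk_raster(c(0, 0.020)))
  expect_equal(nrow(ev3), 2L)
  ev4 <- group_mua(mk_raster(0.5))
  expect_equal(c(ev4$t1, ev4$t2, ev4$n_spikes), c(0.5, 0.5, 1))
})

test_that("every spike belongs to exactly one MUA event (channel and layer scope)", {
  f <- fix_small()
  for (scope in c("channel", "layer")) {
    ev <- group_mua(f$raster, scope = scope)
    expect_equal(sum(ev$n_spikes), sum(lengths(f$raster$times)))
    expect_true(all(ev$t2 >= ev$t1))
  }
  # layer scope pools member channels
  ev_l <- group_mua(f$raster, scope = "layer")
  iv_ch <- f$raster$channels$index[f$raster$channels$layer == "IV"]
  expect_equal(sum(ev_l$n_spikes[ev_l$group == "IV"]),
               sum(lengths(f$raster$times[iv_ch])))
})
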