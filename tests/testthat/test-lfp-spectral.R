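# Signal conditioning and spectral estimation.

test_that("DPSS tapers match the reference Slepian sequences", {
  V <- dpssTapers(64, 3, 5)
  expect_equal(dim(V), c(64L, 5L))
  expect_equal(colSums(V^2), rep(1, 5), tolerance = 1e-12)
  # values computed independently with scipy.signal.windows.dpss(64, 3, 5)
  expect_equal(V[1:6, 1],
    c(0.00035644, 0.00079119, 0.00146828, 0.00245928, 0.00384345,
      0.00570586), tolerance = 1e-4)
  expect_equal(V[21:24, 3],
    c(0.11915027, 0.09135369, 0.06090299, 0.02880812), tolerance = 1e-4)
  expect_error(dpssTapers(64, 3, 8), "2\\*nw")
  expect_error(MultitaperParams(3, 8), "nTapers")
})

test_that("preprocessing is zero-phase, band-limiting and unit-gain in the passband", {
  fs <- 4000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x10 <- sin(2 * pi * 10 * t)
  raw <- LfpRecording(x10 * 100, fs)
  out <- preprocessLfp(raw, hpKernelDur = 3)
  expect_equal(sampleRate(out), 1000)
  y <- samples(out)
  mid <- 5000:25000
  tOut <- (mid - 1) / 1000
  ref <- sin(2 * pi * 10 * tOut) * 100
  # zero phase: peak cross-correlation at lag 0
  cc <- ccf(y[mid], ref, lag.max = 10, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf), 1, 1], 0)
  expect_equal(sd(y[mid]) / sd(ref), 1, tolerance = 0.01)
  # 20 Hz passband gain within 1%
  x20 <- LfpRecording(sin(2 * pi * 20 * t) * 100, fs)
  y20 <- samples(preprocessLfp(x20, hpKernelDur = 3))
  expect_equal(sd(y20[mid]) / sd(100 * sin(2 * pi * 20 * tOut)), 1,
               tolerance = 0.01)
  # 500 Hz attenuated by >= 40 dB
  x500 <- LfpRecording(sin(2 * pi * 500 * t) * 100, fs)
  y500 <- samples(preprocessLfp(x500, hpKernelDur = 3))
  expect_lt(sd(y500[mid]) / (100 / sqrt(2)), 10^(-40 / 20))
  # DC offset removed
  xdc <- LfpRecording(rep(100, length(t)), fs)
  ydc <- samples(preprocessLfp(xdc, hpKernelDur = 3))
  expect_lt(abs(mean(ydc[mid])), 1)
  expect_error(preprocessLfp(LfpRecording(rnorm(100), 4000)), "shorter")
  expect_error(preprocessLfp(LfpRecording(rnorm(1000), 1500)), "2 kHz")
})

test_that("multitaper PSD: null, Parseval, line concentration, time reversal", {
  mt <- MultitaperParams()
  z <- multitaperPsd(rep(0, 1000), mt, fs = 1000)
  expect_true(all(z$psd == 0))
  set.seed(1)
  x <- rnorm(8192)
  p <- multitaperPsd(x, mt, fs = 1000)
  expect_true(all(p$psd >= 0))
  expect_equal(sum(p$psd) * 1000 / 8192, var(x), tolerance = 0.1)
  # 25 Hz line concentrates within the taper half-bandwidth TW/window
  t <- seq(0, 0.999, by = 1e-3)
  ps <- multitaperPsd(sin(2 * pi * 25 * t), mt, fs = 1000)
  expect_lte(abs(ps$freq[which.max(ps$psd)] - 25), 3)
  prev <- multitaperPsd(rev(x), mt, fs = 1000)
  expect_equal(p$psd, prev$psd, tolerance = 1e-8)
})

test_that("band power: selectivity, quadratic scaling, zero null", {
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  lfp <- LfpRecording(sin(2 * pi * 25 * t) * 50, fs)
  beta <- bandPowerTimecourse(lfp, betaBand())
  theta <- bandPowerTimecourse(lfp, thetaBand())
  expect_gt(mean(beta$power) / mean(theta$power), 100)
  # amplitude doubling quadruples band power (exact quadratic scaling)
  lfp2 <- LfpRecording(samples(lfp) * 2, fs)
  beta2 <- bandPowerTimecourse(lfp2, betaBand())
  expect_equal(beta2$power, 4 * beta$power, tolerance = 1e-9)
  z <- bandPowerTimecourse(LfpRecording(rep(0, 30000), fs), betaBand())
  expect_true(all(z$power == 0))
  expect_error(bandPowerTimecourse(lfp, BandSpec("hi", 600, 700, 1, 0.5)),
               "Nyquist")
})

test_that("Morlet spectrogram: 40 log-spaced bins, line and chirp tracking", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  sp0 <- morletSpectrogram(LfpRecording(rep(0, length(t)), fs),
                           tDecim = 50L)
  expect_identical(length(sp0$freq), 40L)
  expect_true(all(sp0$power == 0))
  sp <- morletSpectrogram(LfpRecording(sin(2 * pi * 25 * t), fs),
                          tDecim = 50L)
  mid <- ncol(sp$power) %/% 2
  fPk <- sp$freq[which.max(sp$power[, mid])]
  expect_equal(fPk, sp$freq[which.min(abs(sp$freq - 25))])
  # chirp 5 -> 40 Hz: ridge frequency increases with time
  f0 <- 5; f1 <- 40
  chirp <- sin(2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * max(t))))
  spc <- morletSpectrogram(LfpRecording(chirp, fs), tDecim = 100L)
  cols <- seq(15, ncol(spc$power) - 15, length.out = 8)
  ridge <- spc$freq[apply(spc$power[, round(cols)], 2, which.max)]
  expect_true(all(diff(ridge) >= 0))
  expect_gt(ridge[8], ridge[1])
  expect_error(morletSpectrogram(LfpRecording(rnorm(100), 200)),
               "2x|support")
})

test_that("downsampling preserves 4-30 Hz band power within 2%", {
  fs <- 2000
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  # band-limited test signal: tones well inside 4-30 Hz
  x <- 40 * sin(2 * pi * 8 * t) + 25 * sin(2 * pi * 24 * t + 1)
  pre <- preprocessLfp(LfpRecording(x, fs), hpKernelDur = 3)
  band <- BandSpec("wide", 4, 30, 1, 0)
  bRaw <- mean(bandPowerTimecourse(LfpRecording(x[(5 * fs):(35 * fs)],
    fs), band)$power)
  y <- samples(pre)
  bOut <- mean(bandPowerTimecourse(LfpRecording(y[(5 * 1000):(35 * 1000)],
    1000), band)$power)
  expect_equal(bOut / bRaw, 1, tolerance = 0.02)
})
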