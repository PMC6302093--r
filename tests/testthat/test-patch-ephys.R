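# In vitro analytics: QC, template detection, kinetics, capacitive fit,
# passive properties, AP metrics.

test_that("QC gate applies the access-resistance and leak rules", {
  ss <- genVcSweeps(GroupParams(miniRate = 0),
                    VcGenParams(fs = 5000), 1, seed = 1, sweepDur = 0.2)
  mk <- function(ri, rf, leak) CellRecord(ss, ri, rf, leak)
  expect_true(qcFilter(mk(12, 14, 150))$pass)       # 16.7% change
  r <- qcFilter(mk(14, 14, 100))
  expect_false(r$pass)
  expect_match(r$reasons, "13 MOhm")
  expect_false(qcFilter(mk(12, 15, 100))$pass)      # 25% change
  expect_false(qcFilter(mk(10, 10, 250))$pass)
  expect_identical(qcFilter(mk(NA, 10, 100))$reasons, "incomplete")
  # purity: identical record, identical verdict
  expect_identical(qcFilter(mk(12, 14, 150)), qcFilter(mk(12, 14, 150)))
})

test_that("template detection: nulls, planted events, invariances", {
  fs <- 20000
  tp <- TemplateParams()
  expect_identical(nrow(detectMinis(rep(0, fs), tp, fs = fs)), 0L)
  expect_error(detectMinis(rep(0, 100), tp, fs = fs), "longer")
  # 20 isolated planted events, amp 50, noise SD 2 -> all found within
  # 1 ms, none extra
  set.seed(5)
  kern <- AmygQuant:::miniKernel(fs, 0.5, 15)
  y <- rnorm(20 * fs, 0, 2)
  tEv <- (seq(0.5, 19, length.out = 20)) + round(runif(20, 0, 0.4), 4)
  idx <- round(tEv * fs) + 1
  for (i in idx) {
    sp <- i:(i + length(kern) - 1)
    y[sp] <- y[sp] - 50 * kern
  }
  ev <- detectMinis(y, tp, fs = fs)
  m <- matchEvents(ev$t, (idx - 1) / fs, tol = 1e-3)
  expect_identical(m$tp, 20L)
  # residual detections can only be near-threshold noise crossings of
  # the t-criterion (a handful per minute are expected at threshold 4
  # in white noise); planted events score far above threshold
  isHit <- vapply(ev$t, function(t)
    min(abs((idx - 1) / fs - t)) <= 1e-3, TRUE)
  expect_lte(sum(!isHit), 3)
  expect_true(all(ev$criterion[!isHit] < 6))
  expect_true(all(ev$criterion[isHit] > 20))
  # translation equivariance: shifting the trace shifts event times
  k <- 400L
  ev2 <- detectMinis(c(rnorm(k, 0, 2), y), tp, fs = fs)
  expect_equal(sort(ev2$t), sort(ev$t) + k / fs, tolerance = 1e-3)
  # offset invariance: a constant added to the trace changes nothing
  ev3 <- detectMinis(y + 137, tp, fs = fs)
  expect_equal(ev3$t, ev$t)
  expect_equal(ev3$criterion, ev$criterion, tolerance = 1e-6)
})

test_that("detection recovers planted Poisson trains with high precision and recall", {
  prs <- vapply(1:3, function(s) {
    ss <- genVcSweeps(GroupParams(miniRate = 5, miniAmpMean = 50,
      miniAmpCv = 0.3), VcGenParams(noiseSd = 2), 1, seed = s,
      sweepDur = 20)
    mask <- stepMaskInterval(ss@protocol)
    ev <- detectMinis(getSweep(ss, 1), TemplateParams(), exclude = mask)
    gt <- groundTruth(ss)$events
    m <- matchEvents(ev$t, gt$t[gt$t > mask[1, 2]])
    c(m$precision, m$recall)
  }, numeric(2))
  expect_true(all(prs >= 0.9))
  expect_gt(mean(prs[1, ]), 0.94)
  expect_gt(mean(prs[2, ]), 0.94)
})

test_that("event kinetics recover the generating kernel", {
  fs <- 20000
  kern <- AmygQuant:::miniKernel(fs, 0.5, 15)
  y <- rep(-30, fs)                    # constant holding current
  i0 <- 5001L
  y[i0:(i0 + length(kern) - 1)] <- y[i0:(i0 + length(kern) - 1)] -
    50 * kern
  ek <- eventKinetics(y, data.frame(t = (i0 - 1) / fs),
                      TemplateParams(), fs = fs)
  expect_equal(ek$amplitude, 50, tolerance = 0.5)
  expect_equal(ek$decayTau, 15, tolerance = 0.5)
  expect_gt(ek$riseTimeUs, 300); expect_lt(ek$riseTimeUs, 800)
  # linearity: doubling the event doubles the measured amplitude
  y2 <- rep(-30, fs)
  y2[i0:(i0 + length(kern) - 1)] <- y2[i0:(i0 + length(kern) - 1)] -
    100 * kern
  ek2 <- eventKinetics(y2, data.frame(t = (i0 - 1) / fs),
                       TemplateParams(), fs = fs)
  expect_equal(ek2$amplitude / ek$amplitude, 2, tolerance = 1e-6)
  # an event 2 ms before the next gets its decay flagged
  y3 <- rep(0, fs)
  for (off in c(0L, round(0.002 * fs))) {
    sp <- (i0 + off):(i0 + off + length(kern) - 1)
    y3[sp] <- y3[sp] - 50 * kern[1:length(sp)]
  }
  ek3 <- eventKinetics(y3, data.frame(t = (i0 - 1 + c(0, 0.002 * fs)) /
    fs), TemplateParams(), fs = fs)
  expect_true(ek3$decayFlag[1])
})

test_that("per-cell summary: frequency, CDFs, Poisson interval recovery", {
  ev <- data.frame(t = seq(1, 30, by = 1), amplitude = rep(40, 30))
  s <- perCellSummary(ev, 60)
  expect_equal(s$frequency, 0.5)
  expect_equal(s$meanAmplitude, 40)
  expect_equal(s$ieiCdf(0.999), 0)
  expect_equal(s$ieiCdf(1), 1)
  expect_warning(s0 <- perCellSummary(ev[0, ], 60), "no events")
  expect_equal(s0$frequency, 0)
  set.seed(8)
  tEv <- cumsum(rexp(400, rate = 4))
  sp <- perCellSummary(data.frame(t = tEv, amplitude = 1), max(tEv))
  expect_equal(mean(diff(tEv)), 1 / 4, tolerance = 0.1)
})

test_that("capacitive fit: degenerate, exact and noisy recovery", {
  fs <- 20000
  # constant trace -> pure offset
  const <- Sweep(rep(100, 2000), fs, "vc",
                 protocol = list(stepAmp = 10, stepDur = 0.02,
                                 onset = 0.02))
  f0 <- fitCapacitiveTransient(const)
  expect_equal(f0$Ainf + mean(c(f0$A1, f0$A2)) * 0, f0$Ainf)
  expect_lt(abs(f0$A1) + abs(f0$A2), 1)
  expect_equal(f0$Ainf, 0, tolerance = 1e-6)   # baseline-subtracted
  # noiseless double exponential recovered within 1% (the onset sample
  # holds the pre-step value; decay samples start one sample later)
  ts <- (1:600) / fs * 1000
  ys <- 800 * exp(-ts / 0.3) + 150 * exp(-ts / 2) + 50
  sw <- Sweep(c(rep(0, 201), ys), fs, "vc",
              protocol = list(stepAmp = 10, stepDur = 601 / fs,
                              onset = 200 / fs))
  f1 <- fitCapacitiveTransient(sw)
  expect_equal(f1$A1, 800, tolerance = 8)
  expect_equal(f1$A2, 150, tolerance = 1.5)
  expect_equal(f1$Ainf, 50, tolerance = 0.5)
  expect_equal(f1$tau1, 0.3, tolerance = 0.003)
  expect_equal(f1$tau2, 2, tolerance = 0.02)
  expect_lt(f1$tau1, f1$tau2)
  # with 5 pA noise the median parameter error stays within 10%
  errs <- vapply(1:9, function(s) {
    set.seed(s)
    swN <- Sweep(c(rep(0, 201), ys + rnorm(600, 0, 5)), fs, "vc",
                 protocol = list(stepAmp = 10, stepDur = 601 / fs,
                                 onset = 200 / fs))
    fN <- fitCapacitiveTransient(swN)
    max(abs(c(fN$A1 / 800, fN$tau1 / 0.3, fN$Ainf / 50) - 1))
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("passive properties invert the circuit algebra", {
  # Ohm's-law limit: negligible transient, Ainf = 20 pA at 10 mV
  fit <- list(A1 = 1e-9, A2 = 0, Ainf = 20, tau1 = 0.1, tau2 = 0.1,
              rss = 0, converged = TRUE)
  pp <- passiveProperties(fit, 10)
  expect_equal(pp$rs + pp$rm, 500, tolerance = 1e-6)
  # round trip through generated circuits (the binding invariant)
  set.seed(33)
  for (i in 1:5) {
    rs <- runif(1, 5, 20); rm <- runif(1, 100, 800)
    cm <- runif(1, 15, 45)
    ss <- genVcSweeps(GroupParams(miniRate = 0),
      VcGenParams(rs = rs, rm = rm, cm = cm, noiseSd = 0), 1,
      seed = i, sweepDur = 0.08)
    p <- passiveProperties(fitCapacitiveTransient(ss), 10)
    expect_equal(p$rs, rs, tolerance = 0.05 * rs)
    expect_equal(p$rm, rm, tolerance = 0.05 * rm)
    expect_equal(p$cm, cm, tolerance = 0.05 * cm)
  }
  # peak below steady state is non-physical for this circuit
  bad <- list(A1 = -5, A2 = 0, Ainf = 20, tau1 = 1, tau2 = 1, rss = 0,
              converged = TRUE)
  expect_false(passiveProperties(bad, 10)$ok)
})

test_that("AP metrics: counts match the simulator, LJP correction fixed", {
  vp <- VcGenParams(fs = 10000)
  cc <- genCcSweeps(vp, c(-20, 10, 40, 80, 150), seed = 6)
  gt <- groundTruth(cc)$spikes
  for (i in seq_len(nSweeps(cc))) {
    am <- apMetrics(getSweep(cc, i))
    expect_identical(am$nAps, length(gt[[i]]))
  }
  am <- apMetrics(getSweep(cc, 5))
  expect_equal(am$thresholdRaw - am$threshold, 7.9, tolerance = 1e-9)
  expect_gt(am$firstApAmplitude, 30)
  sub <- apMetrics(getSweep(cc, 1))
  expect_identical(sub$nAps, 0L)
  expect_true(is.na(sub$threshold))
})
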