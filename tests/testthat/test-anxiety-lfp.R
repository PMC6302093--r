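# Behavioral-state LFP analyses.

# A scripted trajectory alternating 30 s center / 30 s periphery bouts,
# always moving, with an LFP whose beta amplitude is multiplied by
# `centerGain` while the animal is in the center.
makeStateFixture <- function(centerGain, fs = 1000, durS = 240,
                             seed = 1) {
  set.seed(seed)
  dt <- 0.1
  tv <- seq(0, durS, by = dt)
  bout <- floor(tv / 30) %% 2 == 0
  x <- ifelse(bout, 5 + 2 * sin(tv), 23)
  y <- ifelse(bout, 5 + 2 * cos(tv), 1.5 * sin(2 * tv))
  traj <- Trajectory(tv, x, y)
  ts <- seq(0, durS - 1 / fs, by = 1 / fs)
  inC <- floor(ts / 30) %% 2 == 0
  amp <- ifelse(inC, 30 * centerGain, 30)
  sig <- amp * sin(2 * pi * 24 * ts) + rnorm(length(ts), 0, 3)
  list(traj = traj, lfp = LfpRecording(sig, fs))
}

test_that("state PSD: null equality and planted center-only beta gain", {
  fx0 <- makeStateFixture(1)
  pC <- statePsd(fx0$lfp, fx0$traj, state = "center")
  pP <- statePsd(fx0$lfp, fx0$traj, state = "periphery")
  sel <- pC$freq >= 18 & pC$freq <= 30
  expect_equal(sum(pC$psd[sel]) / sum(pP$psd[sel]), 1, tolerance = 0.1)
  fx <- makeStateFixture(1.5)
  qC <- statePsd(fx$lfp, fx$traj, state = "center")
  qP <- statePsd(fx$lfp, fx$traj, state = "periphery")
  expect_equal(sum(qC$psd[sel]) / sum(qP$psd[sel]), 2.25,
               tolerance = 0.15 * 2.25)
  outsel <- qC$freq >= 4 & qC$freq <= 12
  expect_equal(sum(qC$psd[outsel]) / sum(qP$psd[outsel]), 1,
               tolerance = 0.5)
  # never entering the center -> empty result with a warning
  still <- Trajectory(seq(0, 240, by = 0.1),
                      rep(23, 2401), seq(-20, 20, length.out = 2401))
  expect_warning(r <- statePsd(fx$lfp, still, state = "center"),
                 "no qualifying")
  expect_identical(nrow(r), 0L)
})

test_that("distance-binned beta: self-normalization and planted gradient", {
  gp0 <- GroupParams(betaDistanceGain = 0, betaSapGain = 1, sapRate = 0)
  cfg <- CohortConfig(list(gp0), seed = 1, sessionDuration = 300)
  tr <- genTrajectory(gp0, cfg, seed = 21)
  pre <- preprocessLfp(genLfp(tr, gp0, LfpGenParams(fsRaw = 2000),
                              seed = 22))
  tc <- bandPowerTimecourse(pre, betaBand())
  db <- distanceBinnedBeta(tc, tr)
  occ <- db[db$occupied, ]
  expect_true(nrow(occ) >= 4)
  expect_true(all(abs(occ$normalizedPower - 1) <= 0.15))
  expect_true(all(is.na(db$normalizedPower[!db$occupied])))
  # planted gain toward the center: decreasing profile, inner bins > 1
  gp1 <- GroupParams(betaDistanceGain = 0.8, betaSapGain = 1,
                     sapRate = 0, centerAvoidance = 0.2)
  tr1 <- genTrajectory(gp1, cfg, seed = 23)
  pre1 <- preprocessLfp(genLfp(tr1, gp1, LfpGenParams(fsRaw = 2000),
                               seed = 24))
  db1 <- distanceBinnedBeta(bandPowerTimecourse(pre1, betaBand()), tr1)
  trend <- betaDistanceTrend(list(db1))
  expect_lt(trend$slope, 0)
  inner <- db1$normalizedPower[db1$occupied][1]
  expect_gt(inner, 1)
  # no periphery occupancy -> normalization rejected
  tcFake <- data.frame(t = seq(5, 50, by = 1), power = 1)
  trC <- Trajectory(seq(0, 60, by = 0.5), rep(0, 121), rep(0, 121))
  expect_error(distanceBinnedBeta(tcFake, trC), "periphery")
})

test_that("trend fit equals closed-form OLS and handles exact profiles", {
  flat <- data.frame(binLo = 0, binHi = 3, binMid = c(2, 5, 8, 11),
    meanPower = 1, normalizedPower = 1, nWindows = 10, occupied = TRUE)
  tr <- betaDistanceTrend(list(flat))
  expect_equal(tr$slope, 0, tolerance = 1e-12)
  # noiseless planted linear profile recovered exactly
  d <- c(2, 5, 8, 11, 14)
  lin <- flat[rep(1, 5), ]
  lin$binMid <- d; lin$normalizedPower <- 2 - 0.05 * d
  expect_equal(betaDistanceTrend(list(lin))$slope, -0.05,
               tolerance = 1e-6)
  # closed-form check on a 5-point toy set
  y <- c(1.2, 0.8, 1.1, 0.9, 1.0)
  toy <- flat[rep(1, 5), ]; toy$binMid <- d; toy$normalizedPower <- y
  slopeHand <- sum((d - mean(d)) * (y - mean(y))) / sum((d - mean(d))^2)
  res <- betaDistanceTrend(list(toy))
  expect_equal(res$slope, slopeHand, tolerance = 1e-12)
  expect_equal(res$r, cor(d, y), tolerance = 1e-12)
  expect_error(betaDistanceTrend(list(flat[1:2, ])), "3 occupied")
})

test_that("speed-binned beta: flat null and planted speed modulation", {
  set.seed(3)
  dt <- 0.1
  tv <- seq(0, 300, by = dt)
  # speed ramps deterministically between 0 and 25 cm/s
  sp <- 12.5 * (1 + sin(2 * pi * tv / 60))
  x <- -20 + cumsum(c(0, diff(tv)) * sp) %% 40
  traj <- Trajectory(tv, x, rep(0, length(tv)))
  tcFlat <- data.frame(t = tv, power = rnorm(length(tv), 100, 5))
  r0 <- speedBinnedBeta(tcFlat, traj)
  expect_lt(abs(r0$slope), 0.5)
  kin <- computeKinematics(traj)
  tcMod <- data.frame(t = tv, power = 50 + 10 * kin$speed)
  r1 <- speedBinnedBeta(tcMod, traj)
  ok <- r1$bins$occupied
  expect_true(all(diff(r1$bins$meanPower[ok]) > 0))
  expect_equal(r1$slope, 10, tolerance = 0.5)
  # a single occupied bin cannot support a trend
  still <- Trajectory(tv, rep(0, length(tv)), rep(0, length(tv)))
  r2 <- speedBinnedBeta(tcFlat, still)
  expect_true(is.na(r2$slope))
})

test_that("SAP-triggered beta: planted doubling, edge cases", {
  # stationary background, amplitude x2 inside events -> power ratio 4
  fs <- 1000
  ts <- seq(0, 120 - 1 / fs, by = 1 / fs)
  saps <- data.frame(tStart = c(20, 50, 90), tEnd = c(23, 52, 93))
  inEv <- rep(FALSE, length(ts))
  for (i in 1:3) inEv[ts >= saps$tStart[i] & ts <= saps$tEnd[i]] <- TRUE
  sig <- ifelse(inEv, 60, 30) * sin(2 * pi * 24 * ts) +
    rnorm(length(ts), 0, 2)
  lfp <- LfpRecording(sig, fs)
  tc <- bandPowerTimecourse(lfp, betaBand(), hop = 0.05)
  # trim windows straddling event edges
  res <- sapTriggeredBeta(tc, saps)
  expect_equal(res$ratio, 4, tolerance = 0.15 * 4)
  expect_identical(nrow(res$perEvent), 3L)
  # no events -> flagged empty
  expect_warning(r0 <- sapTriggeredBeta(tc, saps[0, ]), "no SAP")
  expect_true(is.na(r0$groupMean))
  # event covering the whole record: event mean equals the global mean
  all1 <- sapTriggeredBeta(tc, data.frame(tStart = -1, tEnd = 130))
  expect_equal(all1$groupMean, mean(tc$power), tolerance = 1e-12)
})

test_that("normalization is idempotent and null slopes cover zero", {
  gp0 <- GroupParams(betaDistanceGain = 0, betaSapGain = 1, sapRate = 0,
                     centerAvoidance = 0)
  cfg <- CohortConfig(list(gp0), seed = 1, sessionDuration = 120)
  slopes <- vapply(1:8, function(s) {
    tr <- genTrajectory(gp0, cfg, seed = 100 + s)
    pre <- preprocessLfp(genLfp(tr, gp0, LfpGenParams(fsRaw = 2000),
                                seed = 200 + s), hpKernelDur = 3)
    db <- distanceBinnedBeta(bandPowerTimecourse(pre, betaBand()), tr)
    # idempotence: the window-weighted periphery aggregate of the
    # normalized profile is 1, so dividing by it again is a no-op
    peri <- db$occupied & db$binLo >= 18
    aggr <- sum(db$normalizedPower[peri] * db$nWindows[peri]) /
      sum(db$nWindows[peri])
    expect_equal(db$normalizedPower[peri] / aggr,
                 db$normalizedPower[peri], tolerance = 0.05)
    betaDistanceTrend(list(db))$slope
  }, numeric(1))
  # planted null: mean slope near zero, sign split
  expect_lt(abs(mean(slopes)), 0.01)
})
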