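# Behavioral-state LFP analyses: state-conditioned spectra,
# distance-binned normalized beta, speed control, SAP-triggered beta.

# Assign each power-window center time the nearest trajectory sample.
nearestTrajIndex <- function(tWindows, traj) {
  idx <- findInterval(tWindows, traj@t, all.inside = TRUE)
  lo <- pmax(1L, idx); hi <- pmin(length(traj@t), idx + 1L)
  ifelse(abs(traj@t[lo] - tWindows) <= abs(traj@t[hi] - tWindows), lo, hi)
}

#' State-conditioned mean power spectrum (center vs periphery)
#'
#' Averages multitaper PSDs over sliding windows whose midpoint falls in
#' the requested zone while the animal is moving (speed above the
#' configured threshold).
#'
#' @param lfp preprocessed \linkS4class{LfpRecording} on the trajectory
#'   clock.
#' @param traj \linkS4class{Trajectory}.
#' @param zones \code{\link{ZoneConfig}}.
#' @param state "center" or "periphery".
#' @param window,overlap PSD window and overlap (s).
#' @param mt \code{\link{MultitaperParams}}.
#' @return data.frame (freq, psd, nWindows); zero rows when no window
#'   qualifies.
#' @export
statePsd <- function(lfp, traj, zones = ZoneConfig(),
                     state = c("center", "periphery"), window = 1,
                     overlap = 0.5, mt = MultitaperParams()) {
  state <- match.arg(state)
  fs <- sampleRate(lfp)
  x <- samples(lfp)
  winLen <- round(window * fs)
  hop <- max(1L, round((window - overlap) * fs))
  starts <- seq(1L, length(x) - winLen + 1L, by = hop)
  tc <- lfp@t0 + (starts - 1 + winLen / 2) / fs
  ti <- nearestTrajIndex(tc, traj)
  z <- zoneLabels(traj, zones)[ti]
  mov <- movementMask(traj, zones)[ti]
  use <- which(z == state & mov)
  if (!length(use)) {
    warning("no qualifying windows for state '", state, "'")
    return(data.frame(freq = numeric(), psd = numeric(),
                      nWindows = integer()))
  }
  idx <- outer(0:(winLen - 1L), starts[use], `+`)
  r <- mtPsdMatrix(matrix(x[idx], nrow = winLen), fs, mt)
  data.frame(freq = r$freq, psd = rowMeans(r$psd),
             nWindows = length(use))
}

#' Distance-binned, periphery-normalized beta power
#'
#' Each sliding-window beta power value is assigned the animal's distance
#' from the arena center at the window midpoint; distances are binned at
#' \code{binWidth} (3 cm), bin means are computed, and every bin is
#' divided by the mean power over all windows with distance beyond
#' \code{zones$peripheryMinDist} (18 cm), so the periphery aggregate is 1
#' by construction. Bins visited by fewer than \code{minWindows} windows
#' are flagged and carry NA.
#'
#' @param betaTc band-power time course data.frame (t, power) from
#'   \code{\link{bandPowerTimecourse}}.
#' @param traj \linkS4class{Trajectory}.
#' @param zones \code{\link{ZoneConfig}}.
#' @param binWidth bin width (cm).
#' @param minWindows minimum windows per usable bin.
#' @return data.frame: binLo, binHi, binMid (cm), meanPower,
#'   normalizedPower, nWindows, occupied.
#' @export
distanceBinnedBeta <- function(betaTc, traj, zones = ZoneConfig(),
                               binWidth = 3, minWindows = 3) {
  ti <- nearestTrajIndex(betaTc$t, traj)
  d <- sqrt(traj@x[ti]^2 + traj@y[ti]^2)
  peri <- d > zones$peripheryMinDist
  stopIfNot(any(peri),
    "no periphery windows; periphery normalization undefined")
  norm <- mean(betaTc$power[peri])
  dmax <- traj@arenaSide * sqrt(2) / 2
  edges <- seq(0, ceiling(dmax / binWidth) * binWidth, by = binWidth)
  bin <- cut(d, edges, include.lowest = TRUE, labels = FALSE)
  nW <- tabulate(bin, nbins = length(edges) - 1)
  mp <- rep(NA_real_, length(nW))
  agg <- tapply(betaTc$power, factor(bin, levels = seq_along(nW)), mean)
  mp[!is.na(agg)] <- agg[!is.na(agg)]
  occupied <- nW >= minWindows
  mp[!occupied] <- NA_real_
  data.frame(binLo = edges[-length(edges)], binHi = edges[-1],
             binMid = (edges[-1] + edges[-length(edges)]) / 2,
             meanPower = mp, normalizedPower = mp / norm,
             nWindows = nW, occupied = occupied)
}

#' Linear trend of normalized beta power on distance from center
#'
#' Ordinary least squares of normalized bin power on bin-center distance,
#' pooled across the subjects of a group (matching per-genotype
#' correlation); per-subject slopes are also returned. The sign
#' convention is power-versus-distance: a planted increase of beta toward
#' the center appears as a negative slope.
#'
#' @param binnedList list of \code{\link{distanceBinnedBeta}} results,
#'   one per subject.
#' @return list with \code{slope}, \code{r}, \code{p}, \code{n} (pooled
#'   fit) and \code{perSubject} data.frame of per-subject slopes.
#' @export
betaDistanceTrend <- function(binnedList) {
  if (is.data.frame(binnedList)) binnedList <- list(binnedList)
  pool <- do.call(rbind, lapply(seq_along(binnedList), function(i) {
    b <- binnedList[[i]]
    ok <- b$occupied & !is.na(b$normalizedPower)
    if (sum(ok) == 0) return(NULL)
    data.frame(subject = i, d = b$binMid[ok], y = b$normalizedPower[ok])
  }))
  stopIfNot(!is.null(pool) && nrow(pool) >= 3,
            "need at least 3 occupied bins for a trend")
  fit <- stats::lm(y ~ d, data = pool)
  sm <- summary(fit)
  perSubj <- do.call(rbind, lapply(split(pool, pool$subject), function(g) {
    if (nrow(g) < 3) return(data.frame(subject = g$subject[1],
                                       slope = NA_real_, r = NA_real_))
    f <- stats::lm(y ~ d, data = g)
    data.frame(subject = g$subject[1], slope = stats::coef(f)[2],
               r = stats::cor(g$d, g$y))
  }))
  rownames(perSubj) <- NULL
  list(slope = unname(stats::coef(fit)[2]),
       r = stats::cor(pool$d, pool$y),
       p = sm$coefficients[2, 4],
       n = nrow(pool), perSubject = perSubj)
}

#' Speed-binned beta power with linear trend
#'
#' Beta power averaged in 5 cm/s speed bins (no normalization), with an
#' OLS trend across occupied bins.
#'
#' @param betaTc band-power time course (t, power).
#' @param traj \linkS4class{Trajectory}.
#' @param binWidth speed-bin width (cm/s).
#' @param minWindows minimum windows per usable bin.
#' @return list with \code{bins} data.frame (binMid, meanPower, nWindows,
#'   occupied) and \code{slope}, \code{r}, \code{p} (NA when fewer than 2
#'   occupied bins).
#' @export
speedBinnedBeta <- function(betaTc, traj, binWidth = 5, minWindows = 3) {
  kin <- computeKinematics(traj)
  ti <- nearestTrajIndex(betaTc$t, traj)
  sp <- kin$speed[ti]
  edges <- seq(0, ceiling(max(sp) / binWidth) * binWidth + binWidth,
               by = binWidth)
  bin <- cut(sp, edges, include.lowest = TRUE, labels = FALSE)
  nW <- tabulate(bin, nbins = length(edges) - 1)
  agg <- tapply(betaTc$power, factor(bin, levels = seq_along(nW)), mean)
  mp <- as.numeric(agg)
  occupied <- nW >= minWindows
  mp[!occupied] <- NA_real_
  bins <- data.frame(binMid = (edges[-1] + edges[-length(edges)]) / 2,
                     meanPower = mp, nWindows = nW, occupied = occupied)
  ok <- which(occupied & !is.na(mp))
  if (length(ok) < 2)
    return(list(bins = bins, slope = NA_real_, r = NA_real_,
                p = NA_real_))
  f <- stats::lm(mp[ok] ~ bins$binMid[ok])
  list(bins = bins, slope = unname(stats::coef(f)[2]),
       r = stats::cor(bins$binMid[ok], mp[ok]),
       p = summary(f)$coefficients[2, 4])
}

#' SAP-triggered beta power
#'
#' The summed beta power series is averaged within each SAP interval
#' (per-event means) and the event means averaged into a group value; the
#' mean over all points outside any event is returned as baseline.
#'
#' @param betaSummed per-time-point beta power data.frame (t, power),
#'   typically \code{\link{bandPowerTimecourse}} on a fine hop (50 ms).
#' @param saps data.frame of SAP intervals (tStart, tEnd).
#' @return list with \code{perEvent} (tStart, tEnd, meanPower, n),
#'   \code{groupMean}, \code{baselineMean}, \code{ratio}.
#' @export
sapTriggeredBeta <- function(betaSummed, saps) {
  if (is.null(saps) || nrow(saps) == 0) {
    warning("no SAP events supplied")
    return(list(perEvent = data.frame(tStart = numeric(),
      tEnd = numeric(), meanPower = numeric(), n = integer()),
      groupMean = NA_real_, baselineMean = NA_real_, ratio = NA_real_))
  }
  stopIfNot(all(saps$tEnd > saps$tStart), "need tEnd > tStart")
  inAny <- rep(FALSE, nrow(betaSummed))
  perEvent <- do.call(rbind, lapply(seq_len(nrow(saps)), function(i) {
    inEv <- betaSummed$t >= saps$tStart[i] & betaSummed$t <= saps$tEnd[i]
    inAny[inEv] <<- TRUE
    data.frame(tStart = saps$tStart[i], tEnd = saps$tEnd[i],
               meanPower = if (any(inEv)) mean(betaSummed$power[inEv])
                           else NA_real_,
               n = sum(inEv))
  }))
  groupMean <- mean(perEvent$meanPower, na.rm = TRUE)
  baselineMean <- if (any(!inAny)) mean(betaSummed$power[!inAny]) else
    mean(betaSummed$power)
  list(perEvent = perEvent, groupMean = groupMean,
       baselineMean = baselineMean, ratio = groupMean / baselineMean)
}
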