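# Miniature-PSC detection (sliding template matching), event kinetics,
# per-cell summaries and recording QC.

#' Template parameters for sliding template-matching detection
#'
#' The template is the biexponential
#' \eqn{e(t) = (1 - e^{-t/\tau_{rise}}) e^{-t/\tau_{decay}}}. At every
#' lag the template is optimally scaled and offset by least squares; the
#' detection criterion is the fitted scale divided by its standard error,
#' and an event is called where the criterion crosses the threshold
#' (default 4), with refractory suppression of secondary crossings.
#' Defaults fit inhibitory minis (rise 0.5 ms, decay 15 ms); sEPSC-like
#' events use a faster template (rise 0.2 ms, decay 3 ms).
#'
#' @param riseTau,decayTau template time constants (ms).
#' @param length template length (ms).
#' @param criterionThreshold detection threshold (dimensionless).
#' @param refractory minimum inter-event spacing (ms).
#' @param polarity "negative" (inward currents) or "positive".
#' @return A \code{TemplateParams} list.
#' @export
TemplateParams <- function(riseTau = 0.5, decayTau = 15, length = 45,
                           criterionThreshold = 4, refractory = 5,
                           polarity = c("negative", "positive")) {
  stopIfNot(riseTau < decayTau, "riseTau must be < decayTau")
  stopIfNot(criterionThreshold > 0, "criterionThreshold must be > 0")
  structure(list(riseTau = riseTau, decayTau = decayTau, length = length,
    criterionThreshold = criterionThreshold, refractory = refractory,
    polarity = match.arg(polarity)), class = "TemplateParams")
}

# Clements-Bekkers sliding criterion: per-lag OLS scale/offset of the
# template against the trace; criterion = scale / SE(scale). Computed for
# all lags with running sums (O(n log n)).
templateCriterion <- function(y, e) {
  m <- length(e)
  stopIfNot(m <= length(y), "template longer than the trace")
  Sy <- slidingSum(y, m)
  Syy <- slidingSum(y * y, m)
  Sye <- slidingDot(y, e)
  Se <- sum(e); See <- sum(e * e)
  denom <- See - Se * Se / m
  s <- (Sye - Sy * Se / m) / denom
  c0 <- (Sy - s * Se) / m
  sse <- Syy + s * s * See + m * c0 * c0 -
    2 * (s * Sye + c0 * Sy - s * c0 * Se)
  se <- sqrt(pmax(sse, 0) / (m - 1) / denom)
  crit <- s / se
  crit[!is.finite(crit)] <- 0
  list(criterion = crit, scale = s)
}

#' Detect miniature PSCs by sliding template matching
#'
#' @param sweep voltage-clamp \linkS4class{Sweep} (or numeric trace with
#'   \code{fs}).
#' @param tp \code{\link{TemplateParams}}.
#' @param fs sampling rate, required for numeric input.
#' @param exclude optional 2-column matrix of time intervals (s) to mask
#'   (e.g. the capacitive step transient).
#' @param passes detection passes: with \code{passes = 2} (default) the
#'   events found in the first sweep of the criterion are subtracted
#'   (scaled template at each detected lag) and the residual is scanned
#'   once more, which recovers events masked by a larger neighbor inside
#'   the template window.
#' @return data.frame of candidates: \code{t} (event onset, s),
#'   \code{criterion}, \code{scale} (pA, positive = matches template
#'   polarity).
#' @export
detectMinis <- function(sweep, tp = TemplateParams(), fs = NULL,
                        exclude = NULL, passes = 2) {
  if (is(sweep, "Sweep")) {
    fs <- sampleRate(sweep)
    y <- samples(sweep)
  } else y <- as.numeric(sweep)
  stopIfNot(!is.null(fs), "fs required for numeric input")
  e <- miniKernel(fs, tp$riseTau, tp$decayTau, tp$length)
  if (tp$polarity == "negative") e <- -e
  det <- detectPass(y, e, fs, tp, exclude)
  if (passes >= 2 && nrow(det)) {
    # subtract with a full-length kernel (decayed to < 0.3%), not the
    # detection template, so no step discontinuity is left at the tail
    eFull <- miniKernel(fs, tp$riseTau, tp$decayTau)
    if (tp$polarity == "negative") eFull <- -eFull
    resid <- y
    for (i in seq_len(nrow(det))) {
      k <- round(det$t[i] * fs) + 1L
      span <- k:min(length(resid), k + length(eFull) - 1L)
      resid[span] <- resid[span] - det$scale[i] * eFull[seq_along(span)]
    }
    # conservative re-scan: subtraction residue (scale/lag error of the
    # first pass) can mimic small events, so the second pass only admits
    # strong peaks; genuinely masked events are clean in the residual
    # and score far above threshold
    tp2 <- tp
    tp2$criterionThreshold <- 3 * tp$criterionThreshold
    det2 <- detectPass(resid, e, fs, tp2, exclude)
    if (nrow(det2)) {
      guard <- max(1, tp$refractory) / 1000
      new <- det2[vapply(det2$t, function(t)
        all(abs(det$t - t) > guard), TRUE), , drop = FALSE]
      det <- rbind(det, new)
      det <- det[order(det$t), , drop = FALSE]
      rownames(det) <- NULL
    }
  }
  det
}

# One criterion sweep with peak acceptance rules.
detectPass <- function(y, e, fs, tp, exclude) {
  r <- templateCriterion(y, e)
  crit <- r$criterion
  if (!is.null(exclude) && length(exclude))
    for (i in seq_len(nrow(exclude))) {
      lo <- max(1L, floor(exclude[i, 1] * fs) - length(e) + 1L)
      hi <- min(length(crit), ceiling(exclude[i, 2] * fs) + 1L)
      if (lo <= hi) crit[lo:hi] <- 0
    }
  th <- tp$criterionThreshold
  refr <- max(1L, round(tp$refractory / 1000 * fs))
  # strict local maxima of the criterion above threshold
  nl <- length(crit)
  isPk <- crit > th &
    crit >= c(-Inf, crit[-nl]) & crit > c(crit[-1], -Inf)
  peaks <- which(isPk)
  if (!length(peaks))
    return(data.frame(t = numeric(), criterion = numeric(),
                      scale = numeric()))
  # sequential acceptance with re-arming: a later peak is a new event
  # only if the criterion re-armed in between (fell below threshold/2)
  # or the peak is prominent relative to the intervening valley (a
  # genuine overlapping event re-elevates the criterion several-fold,
  # while noise wiggles on a decaying tail do not)
  keep <- peaks[1]
  last <- peaks[1]
  for (p in peaks[-1]) {
    valley <- min(crit[last:p])
    rearmed <- valley < th / 2 || crit[p] >= 2.5 * valley
    if (p - last >= refr && rearmed) {
      keep <- c(keep, p); last <- p
    } else if (crit[p] > crit[keep[length(keep)]] && p - last < refr) {
      keep[length(keep)] <- p; last <- p
    }
  }
  data.frame(t = (keep - 1) / fs, criterion = crit[keep],
             scale = abs(r$scale[keep]))
}

#' Amplitude and kinetics of detected events
#'
#' Amplitude is peak minus the pre-event baseline (mean over the 2 ms
#' before onset); rise time is the 20-80% interval (linear
#' interpolation); the decay constant comes from a least-squares
#' single-exponential fit from the peak to 90% recovery. Decay is flagged
#' unfit when the next event begins inside the fit span.
#'
#' @param trace numeric voltage-clamp trace (pA) or \linkS4class{Sweep}.
#' @param events data.frame from \code{\link{detectMinis}} (column t).
#' @param tp \code{\link{TemplateParams}} (polarity and search spans).
#' @param fs sampling rate for numeric input.
#' @return data.frame: t (s), amplitude (pA, positive), riseTimeUs,
#'   decayTau (ms, NA when unfit), decayFlag.
#' @export
eventKinetics <- function(trace, events, tp = TemplateParams(),
                          fs = NULL) {
  if (is(trace, "Sweep")) {
    fs <- sampleRate(trace)
    y <- samples(trace)
  } else y <- as.numeric(trace)
  stopIfNot(!is.null(fs), "fs required for numeric input")
  sgn <- if (tp$polarity == "negative") -1 else 1
  n <- length(y)
  searchLen <- round((tp$riseTau * 6 + tp$decayTau) / 1000 * fs)
  out <- lapply(seq_len(nrow(events)), function(i) {
    i0 <- round(events$t[i] * fs) + 1L
    b0 <- max(1L, i0 - round(0.002 * fs)); b1 <- max(1L, i0 - 1L)
    base <- mean(y[b0:b1])
    span <- i0:min(n, i0 + searchLen)
    rel <- sgn * (y[span] - base)
    pk <- which.max(rel)
    amp <- rel[pk]
    # 20-80% rise (interpolated)
    t20 <- crossTime(rel[1:pk], 0.2 * amp)
    t80 <- crossTime(rel[1:pk], 0.8 * amp)
    riseUs <- (t80 - t20) / fs * 1e6
    # decay fit: peak -> 90% recovery, or until the next event
    recov <- which(rel[pk:length(rel)] <= 0.1 * amp)
    endRel <- if (length(recov)) pk + recov[1] - 1 else length(rel)
    fitEnd <- span[1] + endRel - 1
    nextT <- if (i < nrow(events)) events$t[i + 1] else Inf
    flagged <- (span[1] + pk - 1) / fs >= nextT ||
      (fitEnd - 1) / fs > nextT
    decay <- NA_real_
    if (!flagged && endRel - pk >= 4) {
      ts <- ((pk:endRel) - pk) / fs * 1000
      ys <- rel[pk:endRel]
      pos <- ys > 0
      if (sum(pos) >= 4) {
        f <- stats::lm(log(ys[pos]) ~ ts[pos])
        decay <- -1 / stats::coef(f)[2]
        if (!is.finite(decay) || decay <= 0) decay <- NA_real_
      }
    }
    data.frame(t = events$t[i], amplitude = amp, riseTimeUs = riseUs,
               decayTau = decay, decayFlag = flagged)
  })
  if (!length(out))
    return(data.frame(t = numeric(), amplitude = numeric(),
      riseTimeUs = numeric(), decayTau = numeric(),
      decayFlag = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# First upward crossing time (fractional sample index, 0-based) of level
# in a monotone-ish vector.
crossTime <- function(v, level) {
  i <- which(v >= level)[1]
  if (is.na(i) || i == 1) return(0)
  (i - 2) + (level - v[i - 1]) / (v[i] - v[i - 1])
}

#' Per-cell summary of detected events
#'
#' @param events data.frame with \code{t} and \code{amplitude}.
#' @param durationS total analyzed recording time (s).
#' @return list: frequency (Hz), meanAmplitude (pA), \code{ieiCdf} and
#'   \code{ampCdf} empirical CDF functions (NULL when no events), n.
#' @export
perCellSummary <- function(events, durationS) {
  stopIfNot(durationS > 0, "duration must be > 0")
  n <- nrow(events)
  if (n == 0) {
    warning("no events; CDFs empty")
    return(list(frequency = 0, meanAmplitude = NA_real_, ieiCdf = NULL,
                ampCdf = NULL, n = 0L))
  }
  iei <- diff(sort(events$t))
  list(frequency = n / durationS,
       meanAmplitude = mean(events$amplitude),
       ieiCdf = if (length(iei)) stats::ecdf(iei) else NULL,
       ampCdf = stats::ecdf(events$amplitude),
       n = n)
}

#' Detect minis across all sweeps of a SweepSet
#'
#' Runs \code{\link{detectMinis}} on each sweep with the capacitive step
#' transient masked, concatenating event times on the recording-long
#' clock. The analyzable duration excludes the masked spans.
#'
#' @param ss a voltage-clamp \linkS4class{SweepSet}.
#' @param tp \code{\link{TemplateParams}}.
#' @param fit optional \code{CapFit} used to size the step mask.
#' @return list: \code{events} (t on the concatenated clock, criterion,
#'   scale), \code{duration} (s, analyzed), \code{maskPerSweep}.
#' @export
detectMinisSweepSet <- function(ss, tp = TemplateParams(), fit = NULL) {
  mask <- stepMaskInterval(ss@protocol, fit)
  evs <- list()
  durTot <- 0
  for (i in seq_len(nSweeps(ss))) {
    sw <- getSweep(ss, i)
    sweepDur <- duration(sw)
    ev <- detectMinis(sw, tp, exclude = mask)
    if (nrow(ev)) {
      ev$t <- ev$t + (i - 1) * sweepDur
      evs[[length(evs) + 1]] <- ev
    }
    durTot <- durTot + sweepDur - (min(mask[1, 2], sweepDur) - mask[1, 1])
  }
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(t = numeric(), criterion = numeric(), scale = numeric())
  list(events = events, duration = durTot, maskPerSweep = mask)
}

#' Recording quality-control gate
#'
#' Pass requires initial access resistance <= 13 MOhm, a change of at
#' most 20% over the recording, and leak current <= 200 pA.
#'
#' @param cell a \linkS4class{CellRecord}.
#' @return list with \code{pass} and character \code{reasons}.
#' @export
qcFilter <- function(cell) {
  reasons <- character()
  if (!is.finite(cell@raInitial) || !is.finite(cell@raFinal) ||
      !is.finite(cell@leak))
    return(list(pass = FALSE, reasons = "incomplete"))
  if (cell@raInitial > 13)
    reasons <- c(reasons, "initial access resistance > 13 MOhm")
  if (abs(cell@raFinal - cell@raInitial) / cell@raInitial > 0.20)
    reasons <- c(reasons, "access resistance changed by more than 20%")
  if (abs(cell@leak) > 200)
    reasons <- c(reasons, "leak current > 200 pA")
  list(pass = length(reasons) == 0, reasons = reasons)
}
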