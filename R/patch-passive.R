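# Capacitive-transient fitting, passive membrane properties, and action
# potential metrics.

#' Fit the capacitive step transient with a double exponential
#'
#' Sweeps are averaged, the pre-step baseline subtracted, and the onset
#' transient over [step onset, step end] fitted with
#' \deqn{I(t) = A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2} + A_\infty}
#' by nonlinear least squares with multi-start initialization (time
#' constants seeded from a log-linear fit of the baseline-stripped decay,
#' then perturbed). The time-constant ordering tau1 < tau2 is enforced.
#' When the second component is not supported by the data the fit
#' degenerates gracefully (A2 near 0).
#'
#' @param x a \linkS4class{SweepSet} or single \linkS4class{Sweep} with a
#'   step protocol (onset, stepDur in the protocol list).
#' @return list of class \code{CapFit}: A1, A2, Ainf (pA), tau1, tau2
#'   (ms), rss (pA^2), converged, plus the fit window metadata.
#' @export
fitCapacitiveTransient <- function(x) {
  if (is(x, "SweepSet")) {
    stopIfNot(nSweeps(x) >= 1, "need at least one sweep")
    fs <- sampleRate(getSweep(x, 1))
    tr <- rowMeans(vapply(seq_len(nSweeps(x)),
      function(i) samples(getSweep(x, i)),
      numeric(length(samples(getSweep(x, 1))))))
    proto <- x@protocol
  } else {
    fs <- sampleRate(x)
    tr <- samples(x)
    proto <- x@protocol
  }
  onset <- proto$onset %||% 0
  stepDur <- proto$stepDur %||% 0.02
  onIdx <- round(onset * fs) + 1L         # sample at the onset instant
  endIdx <- min(length(tr), onIdx + round(stepDur * fs))
  base <- if (onIdx > 1) mean(tr[max(1, onIdx - round(0.005 * fs)):
                                 (onIdx - 1)]) else 0
  # samples strictly after onset; t measured from the onset instant
  ii <- (onIdx + 1L):endIdx
  ts <- (ii - onIdx) / fs * 1000          # ms
  ys <- tr[ii] - base
  fit <- fitDoubleExp(ts, ys)
  structure(c(fit, list(fs = fs, baseline = base)), class = "CapFit")
}

# Double-exponential-plus-offset least squares with multi-start
# Levenberg-Marquardt (nls.lm on log-tau parameters, which keeps the
# time constants positive without hard bounds).
fitDoubleExp <- function(ts, ys) {
  aInf0 <- mean(ys[ts >= max(ts) * 0.75])
  resid0 <- ys - aInf0
  # seed tau from the early decay: the leading contiguous run of samples
  # still above 10% of the initial residual
  nEarly <- match(FALSE, resid0 > max(abs(resid0)) * 0.1,
                  nomatch = length(resid0) + 1L) - 1L
  early <- seq_len(max(nEarly, 0L))
  tau0 <- if (length(early) >= 3) {
    f <- stats::lm(log(resid0[early]) ~ ts[early])
    max(-1 / stats::coef(f)[2], ts[2] / 4, na.rm = TRUE)
  } else max(ts[2], 0.1)
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(ts[2], 0.1)
  a0 <- max(resid0[1], 1e-3)
  model <- function(p, t)
    p[1] * exp(-t / exp(p[2])) + p[3] * exp(-t / exp(p[4])) + p[5]
  rfun <- function(p) ys - model(p, ts)
  starts <- list(
    c(0.8 * a0, log(tau0 / 2), 0.2 * a0, log(tau0 * 4), aInf0),
    c(a0, log(tau0), a0 / 20, log(tau0 * 10), aInf0),
    c(0.5 * a0, log(tau0 / 4), 0.5 * a0, log(tau0), aInf0),
    c(a0, log(tau0 / 10), a0 / 10, log(tau0), aInf0))
  best <- NULL
  for (st in starts) {
    f <- tryCatch(minpack.lm::nls.lm(st, fn = rfun,
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(f) || !all(is.finite(f$par))) next
    rss <- sum(rfun(f$par)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = f$par, rss = rss)
  }
  if (is.null(best))
    return(list(A1 = NA_real_, A2 = NA_real_, Ainf = NA_real_,
                tau1 = NA_real_, tau2 = NA_real_, rss = NA_real_,
                converged = FALSE))
  p <- best$par
  out <- list(A1 = p[1], tau1 = exp(p[2]), A2 = p[3], tau2 = exp(p[4]),
              Ainf = p[5], rss = best$rss, converged = TRUE)
  if (out$tau1 > out$tau2) {
    out[c("A1", "A2")] <- out[c("A2", "A1")]
    out[c("tau1", "tau2")] <- out[c("tau2", "tau1")]
  }
  out
}

#' Passive membrane properties from a capacitive fit
#'
#' Inverts the step response of the series-resistance (Rs) plus parallel
#' Rm-Cm circuit. At the step instant the capacitor is uncharged, so the
#' peak current is dV/Rs; at steady state the current is dV/(Rs+Rm); and
#' the transient charge fixes the membrane time constant
#' \eqn{\tau = C_m R_s R_m / (R_s + R_m)}, estimated from the fit as the
#' amplitude-weighted time constant (A1 tau1 + A2 tau2)/(A1 + A2).
#'
#' @param fit a \code{CapFit}.
#' @param stepDv step amplitude (mV, > 0).
#' @return list of class \code{PassiveProps}: rs, rm (MOhm), cm (pF),
#'   ok (FALSE with a reason when the algebra yields a non-physical
#'   value).
#' @export
passiveProperties <- function(fit, stepDv = 10) {
  stopIfNot(stepDv > 0, "stepDv must be > 0")
  stopIfNot(isTRUE(fit$converged), "capacitive fit did not converge")
  i0 <- fit$A1 + fit$A2 + fit$Ainf        # pA at t = 0
  iInf <- fit$Ainf
  if (i0 <= 0 || iInf <= 0 || i0 <= iInf)
    return(structure(list(rs = NA_real_, rm = NA_real_, cm = NA_real_,
      ok = FALSE, reason = "non-physical fit amplitudes"),
      class = "PassiveProps"))
  rs <- stepDv / i0 * 1000                # mV/pA = GOhm -> MOhm
  rtot <- stepDv / iInf * 1000
  rm <- rtot - rs
  if (rm <= 0)
    return(structure(list(rs = rs, rm = NA_real_, cm = NA_real_,
      ok = FALSE, reason = "implied negative membrane resistance"),
      class = "PassiveProps"))
  tauW <- (fit$A1 * fit$tau1 + fit$A2 * fit$tau2) / (fit$A1 + fit$A2)
  cm <- tauW * (rs + rm) / (rs * rm) * 1000   # ms/MOhm = nF -> pF
  structure(list(rs = rs, rm = rm, cm = cm, ok = cm > 0,
                 reason = NULL), class = "PassiveProps")
}

#' Action-potential metrics from a current-clamp step sweep
#'
#' Spikes are upward crossings of a dV/dt criterion (default 20 mV/ms,
#' the phase-plane threshold criterion) inside the step window. The
#' firing threshold is the membrane potential at the criterion crossing;
#' the reported threshold subtracts the measured liquid junction
#' potential (7.9 mV). First-AP amplitude is the spike peak minus the
#' threshold potential.
#'
#' @param cc current-clamp \linkS4class{Sweep} with a step protocol.
#' @param dvdtCriterion phase-plane threshold criterion (mV/ms).
#' @param ljp liquid junction potential correction (mV).
#' @return list of class \code{ApMetrics}: nAps, firstApAmplitude (mV),
#'   threshold (LJP-corrected, mV), thresholdRaw, spikeTimes (s).
#' @export
apMetrics <- function(cc, dvdtCriterion = 20, ljp = 7.9) {
  stopIfNot(is(cc, "Sweep") && cc@mode == "cc",
            "need a current-clamp sweep")
  fs <- sampleRate(cc)
  v <- samples(cc)
  onset <- cc@protocol$onset %||% 0
  stepDur <- cc@protocol$stepDur %||% (length(v) / fs - onset)
  dvdt <- c(0, diff(v)) * fs / 1000       # mV/ms
  inStep <- seq_along(v) / fs > onset &
    seq_along(v) / fs <= onset + stepDur + 0.002
  up <- which(dvdt[-1] > dvdtCriterion & dvdt[-length(dvdt)] <=
                dvdtCriterion) + 1L
  up <- up[inStep[up]]
  # merge crossings closer than 2 ms (one AP)
  if (length(up) > 1)
    up <- up[c(TRUE, diff(up) > 0.002 * fs)]
  if (!length(up))
    return(structure(list(nAps = 0L, firstApAmplitude = NA_real_,
      threshold = NA_real_, thresholdRaw = NA_real_,
      spikeTimes = numeric()), class = "ApMetrics"))
  thrRaw <- v[up[1] - 1L]
  pkSpan <- up[1]:min(length(v), up[1] + round(0.005 * fs))
  amp <- max(v[pkSpan]) - thrRaw
  structure(list(nAps = length(up), firstApAmplitude = amp,
    threshold = thrRaw - ljp, thresholdRaw = thrRaw,
    spikeTimes = (up - 1) / fs), class = "ApMetrics")
}

#' Mask interval for the capacitive step transient
#'
#' Returns the time interval [onset, onset + stepDur + 5 tau2] to exclude
#' from mini detection, given a capacitive fit (or a conservative default
#' span when no fit is available).
#'
#' @param proto protocol list with onset and stepDur (s).
#' @param fit optional \code{CapFit} supplying tau2 (ms).
#' @return 1 x 2 matrix of (start, end) times in s.
#' @export
stepMaskInterval <- function(proto, fit = NULL) {
  onset <- proto$onset %||% 0
  stepDur <- proto$stepDur %||% 0.02
  tau2 <- if (!is.null(fit) && isTRUE(fit$converged)) fit$tau2 else 5
  # a contaminated fit can report an absurd slow component; the mask is
  # a transient guard, so cap the extension at 5 x 20 ms
  ext <- 5 * min(tau2, 20) / 1000
  matrix(c(onset, onset + stepDur + ext), nrow = 1)
}
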