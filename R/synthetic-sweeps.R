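# Voltage-clamp and current-clamp sweep generators with planted ground
# truth: two-compartment capacitive step responses, Poisson mini trains,
# and adaptive exponential integrate-and-fire spiking.

# Biexponential mini kernel, unit peak amplitude, t in s.
miniKernel <- function(fs, riseTauMs, decayTauMs, lengthMs = NULL) {
  if (is.null(lengthMs)) lengthMs <- riseTauMs + 6 * decayTauMs
  t <- seq(0, lengthMs / 1000, by = 1 / fs)
  r <- riseTauMs / 1000; d <- decayTauMs / 1000
  k <- (1 - exp(-t / r)) * exp(-t / d)
  k / max(k)
}

# Step-current response of the series-Rs / parallel-Rm-Cm circuit,
# integrated numerically (deSolve). Times in s from the sweep start; the
# command potential steps by stepDv over [onset, onset + stepDur].
# Returns clamp current in pA (excluding leak).
circuitStepCurrent <- function(tVec, rs, rm, cm, stepDv, onsetS, stepDurS) {
  # units: t ms, V mV, R MOhm, C pF, I pA
  # half-open step interval (on, off]: the onset sample still holds the
  # pre-step current, so the sampled peak is strictly below dV/Rs
  deriv <- function(t, y, p) {
    vc <- if (t > p$on && t <= p$off) p$dv else 0
    list(1000 * ((vc - y[1]) / p$rs - y[1] / p$rm) / p$cm)
  }
  tMs <- tVec * 1000
  p <- list(rs = rs, rm = rm, cm = cm, dv = stepDv,
            on = onsetS * 1000, off = (onsetS + stepDurS) * 1000)
  out <- deSolve::lsoda(c(v = 0), times = tMs, func = deriv, parms = p,
    rtol = 1e-10, atol = 1e-10, events = list(times = c(p$on, p$off)))
  vm <- out[, 2]
  vc <- ifelse(tMs > p$on & tMs <= p$off, stepDv, 0)
  1000 * (vc - vm) / rs
}

#' Generate voltage-clamp sweeps with planted minis and a test step
#'
#' Each sweep is the sum of the capacitive response of the two-compartment
#' clamp circuit to the test step (numerically integrated ODE), a Poisson
#' train of negative-going (inward) miniature PSCs convolved with a
#' biexponential kernel, the leak current, and Gaussian noise. Planted
#' event times/amplitudes and the circuit parameters are attached as
#' ground truth.
#'
#' @param gp \code{\link{GroupParams}} (mini rate and amplitudes).
#' @param vp \code{\link{VcGenParams}}.
#' @param nSweeps number of sweeps (>= 1).
#' @param seed integer seed.
#' @param sweepDur sweep duration (s).
#' @return A \linkS4class{SweepSet}; \code{groundTruth()} holds
#'   \code{events} (sweep, t within the concatenated record in s, amp pA),
#'   \code{circuit}, and \code{leak}.
#' @export
genVcSweeps <- function(gp, vp, nSweeps = 1, seed = 1, sweepDur = 2) {
  stopIfNot(nSweeps >= 1, "nSweeps must be >= 1")
  set.seed(seed)
  fs <- vp$fs
  nS <- round(sweepDur * fs)
  tVec <- (seq_len(nS) - 1) / fs
  onset <- 0.01
  stepDurS <- vp$stepDur / 1000
  stepI <- circuitStepCurrent(tVec, vp$rs, vp$rm, vp$cm, vp$stepDv,
                              onset, stepDurS)
  kern <- miniKernel(fs, vp$miniRiseTau, vp$miniDecayTau)
  sweeps <- vector("list", nSweeps)
  evAll <- list()
  for (s in seq_len(nSweeps)) {
    nEv <- stats::rpois(1, gp$miniRate * sweepDur)
    tr <- stepI + vp$leak
    if (nEv > 0) {
      tEv <- sort(stats::runif(nEv, 0, sweepDur - 1e-3))
      cv <- max(gp$miniAmpCv, 1e-6)
      amps <- stats::rgamma(nEv, shape = 1 / cv^2,
                            scale = gp$miniAmpMean * cv^2)
      idx <- floor(tEv * fs) + 1L
      tEv <- (idx - 1) / fs              # snap onsets to the sample grid
      for (j in seq_len(nEv)) {
        span <- idx[j]:min(nS, idx[j] + length(kern) - 1L)
        tr[span] <- tr[span] - amps[j] * kern[seq_along(span)]
      }
      evAll[[s]] <- data.frame(sweep = s, t = (s - 1) * sweepDur + tEv,
                               amp = amps)
    }
    if (vp$noiseSd > 0) tr <- tr + stats::rnorm(nS, 0, vp$noiseSd)
    sweeps[[s]] <- Sweep(tr, fs, "vc",
      protocol = list(stepAmp = vp$stepDv, stepDur = stepDurS,
                      onset = onset))
  }
  events <- if (length(evAll)) do.call(rbind, evAll) else
    data.frame(sweep = integer(), t = numeric(), amp = numeric())
  SweepSet(sweeps,
    protocol = list(stepAmp = vp$stepDv, stepDur = stepDurS,
                    onset = onset, sweepDur = sweepDur, fs = fs),
    groundTruth = list(events = events,
      circuit = list(rs = vp$rs, rm = vp$rm, cm = vp$cm),
      leak = vp$leak, seed = seed))
}

#' Generate current-clamp step sweeps from an adaptive exponential neuron
#'
#' A 500 ms current step is injected into an adaptive exponential
#' integrate-and-fire membrane (Euler integration at the sampling rate).
#' Spike times (threshold-crossing instants) are attached as ground truth;
#' spike count is non-decreasing in step amplitude by construction of the
#' model.
#'
#' @param vp \code{\link{VcGenParams}} (cm and rm set the passive
#'   membrane; the AdEx spiking parameters are fixed, see Details).
#' @param stepAmps step amplitudes (pA), one sweep each.
#' @param seed integer seed.
#' @param stepDur step duration (s).
#' @details AdEx parameters: EL = -70 mV, VT = -50 mV, DeltaT = 2 mV,
#'   reset -58 mV, spike cut 0 mV, adaptation a = 2 nS, b = 30 pA,
#'   tau_w = 100 ms. gL = 1000/rm nS, C = cm pF.
#' @return A \linkS4class{SweepSet} of current-clamp sweeps with
#'   ground-truth spike times per sweep.
#' @export
genCcSweeps <- function(vp, stepAmps, seed = 1, stepDur = 0.5) {
  stopIfNot(length(stepAmps) >= 1, "stepAmps must be non-empty")
  set.seed(seed)
  fs <- vp$fs
  dtMs <- 1000 / fs
  onset <- 0.1
  sweepDur <- onset + stepDur + 0.1
  nS <- round(sweepDur * fs)
  EL <- -70; VT <- -50; dT <- 2; vReset <- -58; vCut <- 0
  aw <- 2; bw <- 30; tauW <- 100
  gL <- 1000 / vp$rm
  C <- vp$cm
  onIdx <- round(onset * fs); offIdx <- round((onset + stepDur) * fs)
  sweeps <- vector("list", length(stepAmps))
  spikesAll <- vector("list", length(stepAmps))
  for (s in seq_along(stepAmps)) {
    V <- numeric(nS); w <- 0
    V[1] <- EL
    spk <- numeric()
    noise <- stats::rnorm(nS, 0, 5)      # small current noise (pA)
    v <- EL
    for (k in 2:nS) {
      I <- if (k > onIdx && k <= offIdx) stepAmps[s] else 0
      expTerm <- gL * dT * exp(min((v - VT) / dT, 20))
      dv <- (-gL * (v - EL) + expTerm - w + I + noise[k]) / C * dtMs
      vNew <- v + dv
      if (vNew >= vCut) {
        # spike: stylized peak, reset, spike-triggered adaptation; the
        # (unbounded) Euler overshoot never enters the w dynamics
        spk <- c(spk, (k - 1) / fs)
        V[k] <- 30
        v <- vReset
        w <- w + (aw * (v - EL) - w) / tauW * dtMs + bw
      } else {
        v <- vNew
        V[k] <- v
        w <- w + (aw * (v - EL) - w) / tauW * dtMs
      }
    }
    sweeps[[s]] <- Sweep(V, fs, "cc",
      protocol = list(stepAmp = stepAmps[s], stepDur = stepDur,
                      onset = onset))
    spikesAll[[s]] <- spk
  }
  SweepSet(sweeps,
    protocol = list(stepAmps = stepAmps, stepDur = stepDur, onset = onset,
                    fs = fs),
    groundTruth = list(spikes = spikesAll, seed = seed,
      adex = list(EL = EL, VT = VT, deltaT = dT, vReset = vReset,
                  a = aw, b = bw, tauW = tauW)))
}
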