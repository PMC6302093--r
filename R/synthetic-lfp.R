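#' Generate an LFP recording with planted position- and SAP-linked beta
#'
#' The signal is the sum of a 1/f^alpha Gaussian background, a theta
#' oscillation with slow amplitude jitter, and a beta oscillation whose
#' instantaneous amplitude carries the planted structure
#' \deqn{A(t) = A_0 (1 + g_d (1 - d(t)/d_{max})) \cdot g_{SAP}(t)}
#' where \eqn{d(t)} is the animal's distance from the arena center
#' (interpolated from the trajectory), \eqn{d_{max}} the half-diagonal of
#' the arena, \eqn{g_d} the planted distance gain and \eqn{g_{SAP}(t)}
#' equal to \code{gp$betaSapGain} inside ground-truth SAP intervals and 1
#' elsewhere. The true amplitude envelope is returned (downsampled to
#' 100 Hz) as ground truth; analyses never read it.
#'
#' @param traj \linkS4class{Trajectory} covering the requested duration.
#' @param gp \code{\link{GroupParams}} (planted gains).
#' @param lp \code{\link{LfpGenParams}}.
#' @param seed integer seed.
#' @return An \linkS4class{LfpRecording}; \code{groundTruth()} carries the
#'   planted envelope.
#' @export
genLfp <- function(traj, gp, lp, seed) {
  stopIfNot(lp$fsRaw >= 2 * lp$betaFreq,
            "fsRaw must be at least twice the beta frequency")
  set.seed(seed)
  fs <- lp$fsRaw
  durS <- duration(traj)
  stopIfNot(durS > 0, "trajectory does not span a positive duration")
  n <- floor(durS * fs)
  tt <- traj@t[1] + (seq_len(n) - 1) / fs
  d <- sqrt(traj@x^2 + traj@y^2)
  dmax <- traj@arenaSide * sqrt(2) / 2
  dOfT <- stats::approx(traj@t, d, xout = tt, rule = 2)$y
  env <- lp$baseBetaAmp * (1 + gp$betaDistanceGain * (1 - dOfT / dmax))
  sap <- sapEvents(traj)
  inSap <- rep(FALSE, n)
  if (nrow(sap))
    for (i in seq_len(nrow(sap)))
      inSap[tt >= sap$tStart[i] & tt <= sap$tEnd[i]] <- TRUE
  env[inSap] <- env[inSap] * gp$betaSapGain
  beta <- env * sin(2 * pi * lp$betaFreq * tt + stats::runif(1, 0, 2 * pi))
  thetaJit <- slowJitter(n, fs, sdRel = 0.2)
  theta <- lp$thetaAmp * (1 + thetaJit) *
    sin(2 * pi * lp$thetaFreq * tt + stats::runif(1, 0, 2 * pi))
  bg <- if (lp$noiseSd > 0)
    oneOverFNoise(n, lp$oneOverFExponent) * lp$noiseSd else numeric(n)
  keep <- seq(1, n, by = max(1L, round(fs / 100)))
  LfpRecording(beta + theta + bg, fs = fs, t0 = traj@t[1],
    meta = list(seed = seed, group = gp$label,
      groundTruth = list(t = tt[keep], betaEnvelope = env[keep],
                         inSap = inSap[keep])))
}

# Smooth zero-mean amplitude jitter: coarse (0.5 Hz) Gaussian knots,
# linearly interpolated to the sample grid.
slowJitter <- function(n, fs, sdRel = 0.2) {
  nk <- max(4L, ceiling(n / fs / 2) + 2L)
  knots <- stats::rnorm(nk, 0, sdRel)
  stats::approx(seq(0, n - 1, length.out = nk), knots, xout = 0:(n - 1))$y
}

# Gaussian noise with a 1/f^alpha amplitude spectrum, unit variance.
oneOverFNoise <- function(n, alpha) {
  N <- nextPow2(n)
  w <- stats::rnorm(N)
  W <- stats::fft(w)
  f <- c(1, seq_len(N - 1))            # avoid the DC singularity
  f <- pmin(f, N - f + 1)              # symmetric shaping
  W <- W * f^(-alpha / 2)
  W[1] <- 0
  x <- Re(stats::fft(W, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}
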