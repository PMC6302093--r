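#' Generate an open-field trajectory with planted center avoidance
#'
#' Positions follow a correlated (Ornstein-Uhlenbeck velocity) random walk
#' reflected at the arena walls. Center avoidance is planted as a radial
#' outward drift on the velocity whose strength is
#' \code{params$centerAvoidance}; zero drift leaves a reflected random
#' walk whose occupancy is close to uniform over the arena. SAP episodes
#' are drawn as a Poisson process at the planted rate, preferentially
#' anchored where the animal sits just outside the center-zone boundary,
#' with durations uniform on 1-3 s; they are returned as ground-truth
#' intervals in the \code{sap} slot.
#'
#' @param params a \code{\link{GroupParams}}.
#' @param cfg a \code{\link{CohortConfig}} (arena side, session duration).
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param dt tracking sample interval (s); 20 Hz by default.
#' @return A \linkS4class{Trajectory} with ground-truth SAP intervals.
#' @export
genTrajectory <- function(params, cfg, seed, dt = 0.05) {
  stopIfNot(cfg$sessionDuration > 0, "session duration must be > 0")
  stopIfNot(cfg$arenaSide > 0, "arena side must be > 0")
  set.seed(seed)
  half <- cfg$arenaSide / 2
  n <- floor(cfg$sessionDuration / dt) + 1L
  tauV <- 0.5                        # velocity correlation time (s)
  sigmaV <- 6.4                      # per-axis stationary speed SD (cm/s)
  sigma <- sigmaV * sqrt(2 / tauV)
  drive <- 20 * params$centerAvoidance   # outward acceleration (cm/s^2)
  x <- y <- vx <- vy <- numeric(n)
  x[1] <- stats::runif(1, -half, half)
  y[1] <- stats::runif(1, -half, half)
  vx[1] <- stats::rnorm(1, 0, sigmaV)
  vy[1] <- stats::rnorm(1, 0, sigmaV)
  ex <- stats::rnorm(n - 1)
  ey <- stats::rnorm(n - 1)
  sdt <- sqrt(dt)
  for (k in seq_len(n - 1)) {
    r <- sqrt(x[k]^2 + y[k]^2)
    ux <- if (r > 1e-9) x[k] / r else 0
    uy <- if (r > 1e-9) y[k] / r else 0
    vx[k + 1] <- vx[k] - vx[k] * dt / tauV + drive * ux * dt +
      sigma * sdt * ex[k]
    vy[k + 1] <- vy[k] - vy[k] * dt / tauV + drive * uy * dt +
      sigma * sdt * ey[k]
    xn <- x[k] + vx[k + 1] * dt
    yn <- y[k] + vy[k + 1] * dt
    if (xn > half)  { xn <- 2 * half - xn; vx[k + 1] <- -vx[k + 1] }
    if (xn < -half) { xn <- -2 * half - xn; vx[k + 1] <- -vx[k + 1] }
    if (yn > half)  { yn <- 2 * half - yn; vy[k + 1] <- -vy[k + 1] }
    if (yn < -half) { yn <- -2 * half - yn; vy[k + 1] <- -vy[k + 1] }
    x[k + 1] <- min(half, max(-half, xn))
    y[k + 1] <- min(half, max(-half, yn))
  }
  tv <- (seq_len(n) - 1) * dt
  sap <- drawSapEpisodes(tv, x, y, params$sapRate, cfg)
  Trajectory(tv, x, y, arenaSide = cfg$arenaSide, sap = sap,
    meta = list(group = params$label, seed = seed, dt = dt))
}

# SAP episodes: Poisson count at the planted rate, start times anchored at
# samples lying in a 4 cm band just outside the center-zone boundary
# (uniform over the session when the band is never visited), duration
# U(1, 3) s, overlaps discarded.
drawSapEpisodes <- function(tv, x, y, sapRate, cfg, centerSide = 37.5) {
  dur <- max(tv)
  nEv <- stats::rpois(1, sapRate * dur / 60)
  if (nEv == 0)
    return(data.frame(tStart = numeric(), tEnd = numeric(),
                      source = character()))
  cheb <- pmax(abs(x), abs(y))
  band <- which(cheb > centerSide / 2 & cheb < centerSide / 2 + 4)
  starts <- if (length(band) >= nEv)
    sort(tv[sample(band, nEv)])
  else sort(stats::runif(nEv, 0, max(0, dur - 3)))
  lens <- stats::runif(nEv, 1, 3)
  ends <- pmin(starts + lens, dur)
  keep <- rep(TRUE, nEv)
  if (nEv > 1)
    for (i in 2:nEv) if (starts[i] < ends[max(which(keep[1:(i - 1)]))])
      keep[i] <- FALSE
  data.frame(tStart = starts[keep], tEnd = ends[keep],
             source = rep("synthetic-ground-truth", sum(keep)))
}
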