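#' Zone configuration for open-field analysis
#'
#' The anxiogenic "center" is an extended square zone of side
#' \code{centerSide} (default 37.5 cm in the 50 cm arena); samples exactly
#' on the boundary count as center (half-open convention). For LFP
#' normalization the periphery is defined radially as > \code{peripheryMinDist}
#' cm from the arena center. Movement means speed above
#' \code{movementSpeedMin}.
#'
#' @param centerSide center-zone side (cm).
#' @param peripheryMinDist radial periphery threshold (cm).
#' @param movementSpeedMin movement-speed threshold (cm/s).
#' @param intermediateBand optional two-element vector (cm from the walls)
#'   defining the reporting-only intermediate zone.
#' @return A \code{ZoneConfig} list.
#' @export
ZoneConfig <- function(centerSide = 37.5, peripheryMinDist = 18,
                       movementSpeedMin = 1,
                       intermediateBand = c(12.5, 25)) {
  stopIfNot(centerSide > 0, "centerSide must be > 0")
  structure(list(centerSide = centerSide,
    peripheryMinDist = peripheryMinDist,
    movementSpeedMin = movementSpeedMin,
    intermediateBand = intermediateBand), class = "ZoneConfig")
}

#' Per-sample kinematics of a trajectory
#'
#' @param traj a \linkS4class{Trajectory} with at least two samples.
#' @return data.frame with \code{t}, \code{speed} (cm/s), \code{step}
#'   (cm, distance covered since the previous sample; 0 at the first),
#'   \code{distFromCenter} (cm). Speed at sample i is the step from
#'   sample i-1 divided by the elapsed time; the first sample repeats the
#'   second's speed so lengths match the input.
#' @export
computeKinematics <- function(traj) {
  n <- length(traj@t)
  stopIfNot(n >= 2, "need at least 2 samples")
  stopIfNot(all(diff(traj@t) > 0), "time must be strictly increasing")
  step <- c(0, sqrt(diff(traj@x)^2 + diff(traj@y)^2))
  dt <- c(NA, diff(traj@t))
  speed <- step / dt
  speed[1] <- speed[2]
  data.frame(t = traj@t, speed = speed, step = step,
             distFromCenter = sqrt(traj@x^2 + traj@y^2))
}

# Per-sample zone labels: "center" or "periphery" (half-open: boundary
# samples are center).
zoneLabels <- function(traj, zones) {
  half <- zones$centerSide / 2
  ifelse(pmax(abs(traj@x), abs(traj@y)) <= half, "center", "periphery")
}

# Debounce a zone sequence: a crossing only counts when at least minRun
# consecutive samples land in the new zone; shorter excursions are
# reassigned to the preceding zone (tracking-jitter suppression).
debounceZones <- function(z, minRun = 2) {
  r <- rle(z)
  if (length(r$lengths) > 1)
    for (i in 2:length(r$lengths))
      if (r$lengths[i] < minRun)
        r$values[i] <- r$values[i - 1]
  z <- inverse.rle(r)
  inverse.rle(rle(z))
}

#' Open-field zone metrics (time, entries, distance)
#'
#' \code{timeInCenter} sums the inter-sample intervals whose left sample
#' lies in the center square; entries count debounced runs of
#' center-zone samples (so a session spent entirely in the center counts
#' one entry); \code{pctDistanceInCenter} is the percentage of the path
#' length travelled while in the center.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param zones a \code{\link{ZoneConfig}}.
#' @return A one-row data.frame: \code{timeInCenter} (s),
#'   \code{pctDistanceInCenter}, \code{centerEntries},
#'   \code{totalDistance} (cm), \code{timeInIntermediate} (s, reporting
#'   only).
#' @export
zoneMetrics <- function(traj, zones = ZoneConfig()) {
  kin <- computeKinematics(traj)
  z <- debounceZones(zoneLabels(traj, zones))
  n <- length(z)
  dt <- diff(traj@t)
  inC <- z == "center"
  timeInCenter <- sum(dt[inC[-n]])
  totalDistance <- sum(kin$step)
  distC <- sum(kin$step[-1][inC[-n]])
  pct <- if (totalDistance > 0) 100 * distC / totalDistance else {
    warning("zero total distance; pctDistanceInCenter set to 0")
    0
  }
  r <- rle(z)
  entries <- sum(r$values == "center")
  wallDist <- traj@arenaSide / 2 - pmax(abs(traj@x), abs(traj@y))
  inInt <- wallDist >= zones$intermediateBand[1] &
    wallDist <= zones$intermediateBand[2]
  data.frame(timeInCenter = timeInCenter,
             pctDistanceInCenter = pct,
             centerEntries = entries,
             totalDistance = totalDistance,
             timeInIntermediate = sum(dt[inInt[-n]]))
}

#' Movement mask (speed above threshold)
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param zones a \code{\link{ZoneConfig}}; threshold in
#'   \code{movementSpeedMin}.
#' @return logical vector, TRUE where speed > threshold.
#' @export
movementMask <- function(traj, zones = ZoneConfig()) {
  computeKinematics(traj)$speed > zones$movementSpeedMin
}

#' Count periphery-to-center transitions
#'
#' Debounced like \code{\link{zoneMetrics}} entries, but an initial
#' center run does not count (only genuine periphery-to-center
#' crossings do).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param zones a \code{\link{ZoneConfig}}.
#' @return integer transition count.
#' @export
countTransitions <- function(traj, zones = ZoneConfig()) {
  z <- debounceZones(zoneLabels(traj, zones))
  r <- rle(z)
  sum(r$values[-1] == "center")
}

#' Behavior summary for a list of subjects
#'
#' @param trajList named list of \linkS4class{Trajectory} objects.
#' @param groups character vector of group labels (recycled if length 1).
#' @param zones a \code{\link{ZoneConfig}}.
#' @return data.frame, one row per subject.
#' @export
behaviorSummary <- function(trajList, groups, zones = ZoneConfig()) {
  rows <- lapply(seq_along(trajList), function(i) {
    cbind(data.frame(subject = names(trajList)[i] %||% i,
                     group = rep(groups, length.out = length(trajList))[i]),
          zoneMetrics(trajList[[i]], zones))
  })
  do.call(rbind, rows)
}
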