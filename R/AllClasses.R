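#' @import methods
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Trajectory: time-stamped 2-D position in the open-field arena frame
#'
#' Positions are expressed in cm with the origin at the arena center and
#' axes parallel to the walls. Ground-truth stretch-attend-posture (SAP)
#' intervals generated alongside synthetic trajectories travel in the
#' \code{sap} slot; analysis code never reads them except for scoring.
#'
#' @slot t numeric, strictly increasing sample times (s).
#' @slot x,y numeric, positions (cm), bounded by the arena walls.
#' @slot arenaSide numeric, side length of the square arena (cm).
#' @slot sap data.frame with columns \code{tStart}, \code{tEnd}, \code{source}
#'   (SAP episodes; may have zero rows).
#' @slot meta list of provenance metadata.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(t = "numeric", x = "numeric", y = "numeric",
    arenaSide = "numeric", sap = "data.frame", meta = "list"),
  prototype(sap = data.frame(tStart = numeric(), tEnd = numeric(),
    source = character()), meta = list()))

setValidity("Trajectory", function(object) {
  msg <- character()
  n <- length(object@t)
  if (length(object@x) != n || length(object@y) != n)
    msg <- c(msg, "t, x, y must have equal length")
  if (n >= 2 && any(diff(object@t) <= 0))
    msg <- c(msg, "t must be strictly increasing")
  if (length(object@arenaSide) != 1 || object@arenaSide <= 0)
    msg <- c(msg, "arenaSide must be a single positive number")
  half <- object@arenaSide / 2 + 1e-6
  if (n > 0 && (any(abs(object@x) > half) || any(abs(object@y) > half)))
    msg <- c(msg, "positions exceed the arena walls")
  if (length(msg)) msg else TRUE
})

#' Construct a Trajectory
#'
#' @param t,x,y numeric vectors (s, cm, cm).
#' @param arenaSide arena side length (cm).
#' @param sap optional data.frame of SAP intervals (tStart, tEnd, source).
#' @param meta optional metadata list.
#' @return A \linkS4class{Trajectory}.
#' @export
Trajectory <- function(t, x, y, arenaSide = 50,
                       sap = NULL, meta = list()) {
  if (is.null(sap))
    sap <- data.frame(tStart = numeric(), tEnd = numeric(),
                      source = character())
  new("Trajectory", t = as.numeric(t), x = as.numeric(x),
      y = as.numeric(y), arenaSide = as.numeric(arenaSide),
      sap = sap, meta = meta)
}

#' LfpRecording: single-channel extracellular voltage time series
#'
#' @slot samples numeric vector of voltage samples (uV).
#' @slot fs sampling rate (Hz).
#' @slot t0 time of the first sample (s).
#' @slot meta list; synthetic recordings carry planted ground truth here
#'   (e.g. the true beta amplitude envelope).
#' @exportClass LfpRecording
setClass("LfpRecording",
  representation(samples = "numeric", fs = "numeric", t0 = "numeric",
    meta = "list"),
  prototype(t0 = 0, meta = list()))

setValidity("LfpRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an LfpRecording
#' @param samples numeric voltage samples (uV).
#' @param fs sampling rate (Hz).
#' @param t0 time of first sample (s).
#' @param meta metadata list.
#' @return An \linkS4class{LfpRecording}.
#' @export
LfpRecording <- function(samples, fs, t0 = 0, meta = list())
  new("LfpRecording", samples = as.numeric(samples), fs = as.numeric(fs),
      t0 = as.numeric(t0), meta = meta)

#' Sweep: one patch-clamp sweep
#'
#' @slot samples numeric trace, pA under voltage clamp or mV under current
#'   clamp.
#' @slot fs sampling rate (Hz).
#' @slot mode "vc" or "cc".
#' @slot protocol list describing the stimulus: \code{stepAmp} (mV in vc,
#'   pA in cc), \code{stepDur} (s), \code{onset} (s from sweep start).
#' @exportClass Sweep
setClass("Sweep",
  representation(samples = "numeric", fs = "numeric", mode = "character",
    protocol = "list"))

setValidity("Sweep", function(object) {
  msg <- character()
  if (length(object@fs) != 1 || object@fs <= 0)
    msg <- c(msg, "fs must be positive")
  if (!object@mode %in% c("vc", "cc"))
    msg <- c(msg, "mode must be 'vc' or 'cc'")
  on <- object@protocol$onset
  if (!is.null(on) && length(object@samples) &&
      (on < 0 || on > length(object@samples) / object@fs))
    msg <- c(msg, "protocol onset must lie within the sweep")
  if (length(msg)) msg else TRUE
})

#' Construct a Sweep
#' @param samples numeric trace (pA for vc, mV for cc).
#' @param fs sampling rate (Hz).
#' @param mode "vc" or "cc".
#' @param protocol stimulus description list (stepAmp, stepDur, onset).
#' @return A \linkS4class{Sweep}.
#' @export
Sweep <- function(samples, fs, mode = c("vc", "cc"), protocol = list())
  new("Sweep", samples = as.numeric(samples), fs = as.numeric(fs),
      mode = match.arg(mode), protocol = protocol)

#' SweepSet: a set of sweeps sharing one protocol
#'
#' @slot sweeps list of \linkS4class{Sweep}.
#' @slot protocol shared stimulus protocol list.
#' @slot groundTruth list; synthetic sets carry planted event times,
#'   amplitudes, circuit parameters or spike times.
#' @exportClass SweepSet
setClass("SweepSet",
  representation(sweeps = "list", protocol = "list", groundTruth = "list"),
  prototype(groundTruth = list()))

setValidity("SweepSet", function(object) {
  if (length(object@sweeps) &&
      !all(vapply(object@sweeps, is, TRUE, "Sweep")))
    return("all elements of sweeps must be Sweep objects")
  TRUE
})

#' Construct a SweepSet
#' @param sweeps list of \linkS4class{Sweep}.
#' @param protocol shared protocol list.
#' @param groundTruth planted ground truth list (synthetic data only).
#' @return A \linkS4class{SweepSet}.
#' @export
SweepSet <- function(sweeps, protocol = list(), groundTruth = list())
  new("SweepSet", sweeps = sweeps, protocol = protocol,
      groundTruth = groundTruth)

#' CellRecord: sweeps plus recording-quality metadata for one cell
#'
#' @slot sweepSet a \linkS4class{SweepSet}.
#' @slot raInitial,raFinal access resistance at start/end (MOhm).
#' @slot leak leak (holding) current (pA).
#' @slot mode one of "vc_mipsc", "vc_sepsc", "cc".
#' @exportClass CellRecord
setClass("CellRecord",
  representation(sweepSet = "SweepSet", raInitial = "numeric",
    raFinal = "numeric", leak = "numeric", mode = "character"))

setValidity("CellRecord", function(object) {
  msg <- character()
  if (length(object@raInitial) == 1 && is.finite(object@raInitial) &&
      object@raInitial <= 0)
    msg <- c(msg, "raInitial must be positive")
  if (length(object@raFinal) == 1 && is.finite(object@raFinal) &&
      object@raFinal <= 0)
    msg <- c(msg, "raFinal must be positive")
  if (!object@mode %in% c("vc_mipsc", "vc_sepsc", "cc"))
    msg <- c(msg, "mode must be vc_mipsc, vc_sepsc or cc")
  if (length(msg)) msg else TRUE
})

#' Construct a CellRecord
#' @param sweepSet a \linkS4class{SweepSet}.
#' @param raInitial,raFinal access resistance (MOhm); NA if not recorded.
#' @param leak leak current (pA); NA if not recorded.
#' @param mode recording mode.
#' @return A \linkS4class{CellRecord}.
#' @export
CellRecord <- function(sweepSet, raInitial = NA_real_, raFinal = NA_real_,
                       leak = NA_real_, mode = "vc_mipsc")
  new("CellRecord", sweepSet = sweepSet, raInitial = as.numeric(raInitial),
      raFinal = as.numeric(raFinal), leak = as.numeric(leak), mode = mode)

#' LabeledImage: one or more fluorescence channels with pixel size
#'
#' Channels are numeric matrices (row-major display convention, origin
#' top-left); intensities are non-negative, 16-bit scale by convention.
#'
#' @slot channels named list of numeric matrices.
#' @slot pixelSize pixel size (um/px).
#' @slot meta list; synthetic images carry planted ground truth here.
#' @exportClass LabeledImage
setClass("LabeledImage",
  representation(channels = "list", pixelSize = "numeric", meta = "list"),
  prototype(meta = list()))

setValidity("LabeledImage", function(object) {
  msg <- character()
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (!length(object@channels) ||
      !all(vapply(object@channels, is.matrix, TRUE)))
    msg <- c(msg, "channels must be a non-empty list of matrices")
  else if (any(vapply(object@channels, function(m) any(m < 0), TRUE)))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledImage
#' @param channels named list of numeric intensity matrices.
#' @param pixelSize um per pixel.
#' @param meta metadata list.
#' @return A \linkS4class{LabeledImage}.
#' @export
LabeledImage <- function(channels, pixelSize, meta = list()) {
  if (is.matrix(channels)) channels <- list(ch1 = channels)
  new("LabeledImage", channels = channels, pixelSize = as.numeric(pixelSize),
      meta = meta)
}

#' RoiSet: closed polygon regions of interest in image coordinates (um)
#'
#' @slot polygons list of two-column matrices (x, y in um), each a simple
#'   closed polygon (last vertex implicitly joined to the first).
#' @slot meta list (ground truth for synthetic sets).
#' @exportClass RoiSet
setClass("RoiSet",
  representation(polygons = "list", meta = "list"),
  prototype(meta = list()))

setValidity("RoiSet", function(object) {
  ok <- vapply(object@polygons, function(p)
    is.matrix(p) && ncol(p) == 2 && nrow(p) >= 3, TRUE)
  if (length(object@polygons) && !all(ok))
    return("each polygon must be a matrix with 2 columns and >= 3 vertices")
  TRUE
})

#' Construct a RoiSet
#' @param polygons list of two-column vertex matrices (um).
#' @param meta metadata list.
#' @return A \linkS4class{RoiSet}.
#' @export
RoiSet <- function(polygons, meta = list()) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  new("RoiSet", polygons = polygons, meta = meta)
}
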