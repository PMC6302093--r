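#' @describeIn accessors LFP voltage samples (uV).
#' @export
setMethod("samples", "LfpRecording", function(object, ...) object@samples)

#' @describeIn accessors Sweep trace.
#' @export
setMethod("samples", "Sweep", function(object, ...) object@samples)

#' @describeIn accessors LFP sampling rate.
#' @export
setMethod("sampleRate", "LfpRecording", function(object, ...) object@fs)

#' @describeIn accessors Sweep sampling rate.
#' @export
setMethod("sampleRate", "Sweep", function(object, ...) object@fs)

#' @describeIn accessors LFP duration (s).
#' @export
setMethod("duration", "LfpRecording",
          function(object, ...) length(object@samples) / object@fs)

#' @describeIn accessors Sweep duration (s).
#' @export
setMethod("duration", "Sweep",
          function(object, ...) length(object@samples) / object@fs)

#' @describeIn accessors Session duration (s) spanned by the trajectory.
#' @export
setMethod("duration", "Trajectory", function(object, ...) {
  if (length(object@t) < 2) return(0)
  diff(range(object@t))
})

#' @describeIn accessors Trajectory samples as a data.frame (t, x, y).
#' @export
setMethod("coords", "Trajectory", function(object, ...)
  data.frame(t = object@t, x = object@x, y = object@y))

#' @describeIn accessors SAP intervals attached to a trajectory.
#' @export
setMethod("sapEvents", "Trajectory", function(object, ...) object@sap)

#' @describeIn accessors Arena side length (cm).
#' @export
setMethod("arenaSide", "Trajectory", function(object, ...) object@arenaSide)

#' @describeIn accessors Number of sweeps in a SweepSet.
#' @export
setMethod("nSweeps", "SweepSet", function(object, ...) length(object@sweeps))

#' @describeIn accessors Extract one sweep.
#' @export
setMethod("getSweep", "SweepSet", function(object, i, ...) object@sweeps[[i]])

#' @describeIn accessors Planted ground truth of a synthetic SweepSet.
#' @export
setMethod("groundTruth", "SweepSet", function(object, ...) object@groundTruth)

#' @describeIn accessors Planted ground truth of a synthetic LfpRecording.
#' @export
setMethod("groundTruth", "LfpRecording", function(object, ...)
  object@meta$groundTruth)

#' @describeIn accessors Planted ground truth of a synthetic LabeledImage.
#' @export
setMethod("groundTruth", "LabeledImage", function(object, ...)
  object@meta$groundTruth)

#' @describeIn accessors Channel names of a LabeledImage.
#' @export
setMethod("channelNames", "LabeledImage",
          function(object, ...) names(object@channels))

#' @describeIn accessors Extract an image channel matrix.
#' @export
setMethod("getChannel", "LabeledImage",
          function(object, name, ...) object@channels[[name]])

#' @describeIn accessors Pixel size (um/px).
#' @export
setMethod("pixelSize", "LabeledImage", function(object, ...)
  object@pixelSize)

#' @describeIn accessors ROI polygon list.
#' @export
setMethod("polygons", "RoiSet", function(object, ...) object@polygons)

#' @describeIn accessors Perimeter length (um) of each ROI polygon.
#' @export
setMethod("perimeterLengths", "RoiSet", function(object, ...)
  vapply(object@polygons, polygonPerimeter, numeric(1)))

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@t), "samples,",
      sprintf("%.1f s,", duration(object)),
      sprintf("arena %g x %g cm,", object@arenaSide, object@arenaSide),
      nrow(object@sap), "SAP episode(s)\n")
})

setMethod("show", "LfpRecording", function(object) {
  cat("LfpRecording:", length(object@samples), "samples at",
      object@fs, "Hz,", sprintf("%.1f s\n", duration(object)))
})

setMethod("show", "Sweep", function(object) {
  cat("Sweep (", object@mode, "): ", length(object@samples),
      " samples at ", object@fs, " Hz\n", sep = "")
})

setMethod("show", "SweepSet", function(object) {
  cat("SweepSet:", length(object@sweeps), "sweep(s)")
  if (length(object@groundTruth)) cat(" [with planted ground truth]")
  cat("\n")
})

setMethod("show", "CellRecord", function(object) {
  cat("CellRecord (", object@mode, "): ", nSweeps(object@sweepSet),
      " sweep(s), Ra ", object@raInitial, " -> ", object@raFinal,
      " MOhm, leak ", object@leak, " pA\n", sep = "")
})

setMethod("show", "LabeledImage", function(object) {
  d <- dim(object@channels[[1]])
  cat("LabeledImage:", length(object@channels), "channel(s),",
      d[1], "x", d[2], "px at", object@pixelSize, "um/px\n")
})

setMethod("show", "RoiSet", function(object) {
  cat("RoiSet:", length(object@polygons), "polygon(s)\n")
})
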