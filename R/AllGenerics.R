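#' Accessor generics
#'
#' Small accessor layer over the data classes: \code{samples} returns the
#' raw trace, \code{sampleRate} the sampling rate (Hz), \code{duration}
#' the record length (s), \code{coords} a data.frame of trajectory
#' samples, \code{sapEvents} the attached SAP intervals, \code{arenaSide}
#' the arena side (cm), \code{nSweeps}/\code{getSweep} the sweep list,
#' \code{channelNames}/\code{getChannel} the image channels,
#' \code{pixelSize} the pixel size (um/px), \code{polygons} the ROI
#' polygons and \code{perimeterLengths} their perimeters (um).
#'
#' @param object an AmygQuant data object.
#' @param ... passed on to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object, ...) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object, ...) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("duration", function(object, ...) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("coords", function(object, ...) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("sapEvents", function(object, ...) standardGeneric("sapEvents"))
#' @rdname accessors
#' @export
setGeneric("arenaSide", function(object, ...) standardGeneric("arenaSide"))
#' @rdname accessors
#' @export
setGeneric("nSweeps", function(object, ...) standardGeneric("nSweeps"))
#' @rdname accessors
#' @param i sweep index.
#' @export
setGeneric("getSweep", function(object, i, ...) standardGeneric("getSweep"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object, ...) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("channelNames",
           function(object, ...) standardGeneric("channelNames"))
#' @rdname accessors
#' @param name channel name or index.
#' @export
setGeneric("getChannel",
           function(object, name, ...) standardGeneric("getChannel"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object, ...) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("polygons", function(object, ...) standardGeneric("polygons"))
#' @rdname accessors
#' @export
setGeneric("perimeterLengths",
           function(object, ...) standardGeneric("perimeterLengths"))
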