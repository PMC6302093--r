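# Readers and writers for the on-disk interchange formats: trajectory
# CSV, LFP float32 binary + JSON sidecar, sweep CSV + JSON protocol,
# 16-bit TIFF images, ROI/ground-truth JSON.

#' Trajectory CSV I/O
#'
#' Columns \code{t_s}, \code{x_cm}, \code{y_cm}; the arena side is kept
#' in a commented header line.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path file path.
#' @return \code{readTrajectoryCsv} returns a \linkS4class{Trajectory}.
#' @export
writeTrajectoryCsv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# arena_side_cm=%g", traj@arenaSide), con)
  utils::write.csv(data.frame(t_s = traj@t, x_cm = traj@x,
                              y_cm = traj@y), con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCsv
#' @param arenaSide arena side (cm), overriding the header comment.
#' @export
readTrajectoryCsv <- function(path, arenaSide = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(arenaSide) && grepl("arena_side_cm=", first))
    arenaSide <- as.numeric(sub(".*arena_side_cm=", "", first))
  d <- utils::read.csv(path, comment.char = "#")
  Trajectory(d$t_s, d$x_cm, d$y_cm, arenaSide = arenaSide %||% 50)
}

#' LFP binary I/O (float32 little-endian + JSON sidecar)
#'
#' @param lfp an \linkS4class{LfpRecording}.
#' @param path data file path; the sidecar is \code{path + ".json"}.
#' @return \code{readLfpBinary} returns an \linkS4class{LfpRecording}.
#' @export
writeLfpBinary <- function(lfp, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(samples(lfp)), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(list(fs_hz = sampleRate(lfp), units = "uV",
    t0_s = lfp@t0, n_samples = length(samples(lfp)), channel = "lfp"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLfpBinary
#' @export
readLfpBinary <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  x <- readBin(con, numeric(), n = side$n_samples, size = 4,
               endian = "little")
  close(con)
  LfpRecording(x, fs = side$fs_hz, t0 = side$t0_s %||% 0)
}

#' SweepSet CSV I/O (stacked sweeps + JSON protocol sidecar)
#'
#' @param ss a \linkS4class{SweepSet}.
#' @param path CSV path (columns sweep, i, value); protocol and ground
#'   truth go to \code{path + ".json"}.
#' @param mode sweep mode for \code{readSweepSetCsv}.
#' @return \code{readSweepSetCsv} returns a \linkS4class{SweepSet}.
#' @export
writeSweepSetCsv <- function(ss, path) {
  rows <- do.call(rbind, lapply(seq_len(nSweeps(ss)), function(i) {
    s <- getSweep(ss, i)
    data.frame(sweep = i, i = seq_along(samples(s)), value = samples(s))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  jsonlite::write_json(list(protocol = ss@protocol,
    fs = sampleRate(getSweep(ss, 1)), mode = getSweep(ss, 1)@mode,
    groundTruth = ss@groundTruth), paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname writeSweepSetCsv
#' @export
readSweepSetCsv <- function(path, mode = NULL) {
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  d <- utils::read.csv(path)
  mode <- mode %||% side$mode
  proto <- as.list(side$protocol)
  sweeps <- lapply(split(d$value, d$sweep), function(v)
    Sweep(v, fs = side$fs, mode = mode, protocol = proto))
  names(sweeps) <- NULL
  gt <- side$groundTruth
  if (!is.null(gt$events)) gt$events <- as.data.frame(gt$events)
  SweepSet(sweeps, protocol = proto, groundTruth = as.list(gt))
}

#' 16-bit TIFF image I/O
#'
#' Channels are written as separate TIFFs (\code{path_<channel>.tif})
#' plus a JSON sidecar carrying the pixel size.
#'
#' @param img a \linkS4class{LabeledImage}.
#' @param pathStem path stem without extension.
#' @return \code{readImageTiff} returns a \linkS4class{LabeledImage}.
#' @export
writeImageTiff <- function(img, pathStem) {
  for (ch in channelNames(img)) {
    m <- getChannel(img, ch) / 65535
    m[m < 0] <- 0
    m[m > 1] <- 1
    tiff::writeTIFF(m, sprintf("%s_%s.tif", pathStem, ch),
                    bits.per.sample = 16L)
  }
  jsonlite::write_json(list(pixel_size_um = pixelSize(img),
    channels = as.list(channelNames(img))),
    paste0(pathStem, ".json"), auto_unbox = TRUE)
  invisible(pathStem)
}

#' @rdname writeImageTiff
#' @export
readImageTiff <- function(pathStem) {
  side <- jsonlite::read_json(paste0(pathStem, ".json"),
                              simplifyVector = TRUE)
  chans <- lapply(side$channels, function(ch)
    tiff::readTIFF(sprintf("%s_%s.tif", pathStem, ch)) * 65535)
  names(chans) <- unlist(side$channels)
  LabeledImage(chans, pixelSize = side$pixel_size_um)
}

#' ROI polygon JSON I/O
#'
#' @param roi a \linkS4class{RoiSet}.
#' @param path JSON path.
#' @return \code{readRoiJson} returns a \linkS4class{RoiSet}.
#' @export
writeRoiJson <- function(roi, path) {
  jsonlite::write_json(lapply(polygons(roi), function(p)
    list(x = p[, 1], y = p[, 2])), path, digits = NA)
  invisible(path)
}

#' @rdname writeRoiJson
#' @export
readRoiJson <- function(path) {
  polys <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(polys)) polys <- split(polys, seq_len(nrow(polys)))
  RoiSet(unname(lapply(polys, function(p)
    cbind(unlist(p$x), unlist(p$y)))))
}

#' SAP annotation CSV I/O
#'
#' @param saps data.frame (tStart, tEnd).
#' @param path CSV path (columns t_start_s, t_end_s).
#' @return \code{readSapCsv} returns the annotation data.frame.
#' @export
writeSapCsv <- function(saps, path) {
  utils::write.csv(data.frame(t_start_s = saps$tStart,
    t_end_s = saps$tEnd), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSapCsv
#' @export
readSapCsv <- function(path) {
  d <- utils::read.csv(path)
  data.frame(tStart = d$t_start_s, tEnd = d$t_end_s,
             source = "annotation")
}
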