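# Rule-based quantification: cFos-positive cells (3x background
# threshold), spot colocalization, and perisomatic puncta density.

# Threshold + connected components with an area gate (um^2). Returns
# centroids in um (x = column, y = row) and areas.
labelComponents <- function(mat, threshold, pixelSize, minAreaUm2,
                            maxAreaUm2) {
  bw <- EBImage::bwlabel(mat > threshold)
  if (max(bw) == 0)
    return(data.frame(x = numeric(), y = numeric(), area = numeric()))
  lab <- as.integer(bw)
  keepPix <- lab > 0
  lab <- lab[keepPix]
  # matrix is indexed [row, col]; EBImage transposes display only
  rc <- arrayInd(which(keepPix), dim(mat))
  areaPx <- tabulate(lab)
  cx <- tapply(rc[, 2], lab, mean)
  cy <- tapply(rc[, 1], lab, mean)
  areaUm2 <- areaPx * pixelSize^2
  ok <- areaUm2 >= minAreaUm2 & areaUm2 <= maxAreaUm2
  data.frame(x = (as.numeric(cx) - 0.5) * pixelSize,
             y = (as.numeric(cy) - 0.5) * pixelSize,
             area = areaUm2)[ok, , drop = FALSE]
}

#' Count cFos-positive cells (3x-background threshold rule)
#'
#' The channel is binarized at three times the background intensity and
#' connected components with plausible nuclear areas are counted as
#' positive cells.
#'
#' @param img \linkS4class{LabeledImage}.
#' @param background background intensity (> 0); when NULL, estimated as
#'   the histogram mode.
#' @param channel channel name or index.
#' @param minArea,maxArea component area gate (um^2).
#' @return list: n, centroids data.frame (x, y in um, area um^2),
#'   threshold, usable (FALSE when >= 99% of pixels exceed threshold).
#' @export
countCfos <- function(img, background = NULL, channel = 1,
                      minArea = 20, maxArea = 300) {
  m <- getChannel(img, channel)
  if (is.null(background)) {
    h <- graphics::hist(m, breaks = 256, plot = FALSE)
    background <- h$mids[which.max(h$counts)]
  }
  stopIfNot(background > 0, "background must be > 0")
  thr <- 3 * background
  if (mean(m >= thr) >= 0.99) {
    warning("saturated image: >= 99% of pixels above threshold")
    return(list(n = NA_integer_, centroids = NULL, threshold = thr,
                usable = FALSE))
  }
  cent <- labelComponents(m, thr, pixelSize(img), minArea, maxArea)
  list(n = nrow(cent), centroids = cent, threshold = thr, usable = TRUE)
}

#' Colocalize two spot sets by greedy one-to-one matching
#'
#' Candidate pairs within \code{radius} are matched greedily in order of
#' increasing distance, each spot used at most once.
#'
#' @param a,b data.frames with x, y (um) in the same coordinate frame.
#' @param radius matching radius (um, >= 0).
#' @return list: n (double-positive count), pairs data.frame (ia, ib,
#'   dist).
#' @export
colocalizeSpots <- function(a, b, radius = 2) {
  stopIfNot(radius >= 0, "radius must be >= 0")
  if (!nrow(a) || !nrow(b))
    return(list(n = 0L, pairs = data.frame(ia = integer(),
      ib = integer(), dist = numeric())))
  dmat <- outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2
  cand <- which(dmat <= radius^2, arr.ind = TRUE)
  if (!nrow(cand))
    return(list(n = 0L, pairs = data.frame(ia = integer(),
      ib = integer(), dist = numeric())))
  ord <- order(dmat[cand])
  usedA <- logical(nrow(a)); usedB <- logical(nrow(b))
  pairs <- list()
  for (k in ord) {
    ia <- cand[k, 1]; ib <- cand[k, 2]
    if (usedA[ia] || usedB[ib]) next
    usedA[ia] <- TRUE; usedB[ib] <- TRUE
    pairs[[length(pairs) + 1]] <- data.frame(ia = ia, ib = ib,
      dist = sqrt(dmat[ia, ib]))
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(ia = integer(), ib = integer(), dist = numeric())
  list(n = nrow(pairs), pairs = pairs)
}

#' Perisomatic puncta density in an annulus around each soma
#'
#' The channel is binarized at a constant threshold (kept fixed across a
#' comparison set), components are gated by area, and those whose
#' centroid lies within the annulus obtained by offsetting the traced
#' perimeter by \code{expansion} um in each direction (inward and
#' outward) are counted. Density is count divided by the perimeter
#' length.
#'
#' @param img \linkS4class{LabeledImage}.
#' @param roi \linkS4class{RoiSet} of soma perimeter polygons (um).
#' @param expansion annulus half-width (um); 1.4 for postsynaptic and
#'   2.0 for presynaptic markers.
#' @param threshold binarization intensity.
#' @param channel channel name or index.
#' @param minArea,maxArea punctum area gate (um^2).
#' @param symmetric when FALSE, count only the outward band.
#' @return data.frame, one row per soma: nPuncta, perimeter (um),
#'   density (puncta/um), meanSize (um^2), skipped.
#' @export
perisomaticPuncta <- function(img, roi, expansion = 1.4, threshold,
                              channel = 1, minArea = 0.05, maxArea = 3,
                              symmetric = TRUE) {
  stopIfNot(expansion > 0, "expansion must be > 0")
  m <- getChannel(img, channel)
  px <- pixelSize(img)
  lim <- dim(m) * px
  cent <- labelComponents(m, threshold, px, minArea, maxArea)
  out <- lapply(polygons(roi), function(poly) {
    per <- polygonPerimeter(poly)
    if (any(poly[, 1] - expansion < 0) || any(poly[, 2] - expansion < 0) ||
        any(poly[, 1] + expansion > lim[2]) ||
        any(poly[, 2] + expansion > lim[1])) {
      warning("polygon leaves the image after expansion; soma skipped")
      return(data.frame(nPuncta = NA_integer_, perimeter = per,
        density = NA_real_, meanSize = NA_real_, skipped = TRUE))
    }
    if (!nrow(cent))
      return(data.frame(nPuncta = 0L, perimeter = per, density = 0,
        meanSize = NA_real_, skipped = FALSE))
    sd <- signedDistanceToPolygon(cent$x, cent$y, poly)
    inAnn <- if (symmetric) abs(sd) <= expansion else
      sd >= 0 & sd <= expansion
    data.frame(nPuncta = sum(inAnn), perimeter = per,
      density = sum(inAnn) / per,
      meanSize = if (any(inAnn)) mean(cent$area[inAnn]) else NA_real_,
      skipped = FALSE)
  })
  do.call(rbind, out)
}

#' Rasterized annulus mask around a polygon
#'
#' Pixels whose centers lie within \code{expansion} um of the polygon
#' boundary (symmetric band). Used for geometry checks; for a circle of
#' radius r the band area is 4 pi r d.
#'
#' @param dims image dimensions (rows, cols).
#' @param pixelSize um/px.
#' @param poly polygon vertex matrix (um).
#' @param expansion band half-width (um).
#' @return logical matrix of the same dimensions.
#' @export
annulusMask <- function(dims, pixelSize, poly, expansion) {
  xs <- ((1:dims[2]) - 0.5) * pixelSize
  ys <- ((1:dims[1]) - 0.5) * pixelSize
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  sd <- signedDistanceToPolygon(gx, gy, poly)
  matrix(abs(sd) <= expansion, nrow = dims[1])
}
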