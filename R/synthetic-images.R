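# Synthetic fluorescence images with planted, machine-readable ground
# truth: cFos-like nuclei above/below the 3x-background threshold,
# perisomatic puncta around a traced soma, and two-channel spot fields
# for colocalization.

# Render Gaussian blobs onto an image matrix (row = y, col = x, px).
renderBlobs <- function(img, cx, cy, sigmaPx, peak) {
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_along(cx)) {
    r0 <- max(1, floor(cy[i] - 4 * sigmaPx[i]))
    r1 <- min(nr, ceiling(cy[i] + 4 * sigmaPx[i]))
    c0 <- max(1, floor(cx[i] - 4 * sigmaPx[i]))
    c1 <- min(nc, ceiling(cx[i] + 4 * sigmaPx[i]))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    g <- outer(exp(-(rr - cy[i])^2 / (2 * sigmaPx[i]^2)),
               exp(-(cc - cx[i])^2 / (2 * sigmaPx[i]^2)))
    img[rr, cc] <- img[rr, cc] + peak[i] * g
  }
  img
}

# Render flat-top disks with a soft (Gaussian-rolloff) edge.
renderDisks <- function(img, cx, cy, radiusPx, edgePx, peak) {
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_along(cx)) {
    ext <- radiusPx[i] + 4 * edgePx
    r0 <- max(1, floor(cy[i] - ext)); r1 <- min(nr, ceiling(cy[i] + ext))
    c0 <- max(1, floor(cx[i] - ext)); c1 <- min(nc, ceiling(cx[i] + ext))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d <- sqrt(outer((rr - cy[i])^2, (cc - cx[i])^2, `+`))
    prof <- ifelse(d <= radiusPx[i], 1,
                   exp(-(d - radiusPx[i])^2 / (2 * edgePx^2)))
    img[rr, cc] <- img[rr, cc] + peak[i] * prof
  }
  img
}

# Rejection-sample n points with pairwise separation >= minSep inside
# [lo, hi]^2 (px).
placeSeparated <- function(n, lo, hi, minSep, maxTries = 4000) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(pts) < n && tries < maxTries) {
    cand <- stats::runif(2, lo, hi)
    if (!nrow(pts) || all((pts[, 1] - cand[1])^2 +
                          (pts[, 2] - cand[2])^2 >= minSep^2))
      pts <- rbind(pts, cand)
    tries <- tries + 1
  }
  pts
}

#' Generate a synthetic fluorescence image with planted ground truth
#'
#' Three kinds are supported. \code{"cfos"}: round nuclei on a flat
#' background, with intensities drawn deliberately above or below 3x the
#' background so the planted positive count is unambiguous.
#' \code{"puncta"}: a dark soma ringed by bright puncta; the traced soma
#' perimeter polygon is returned as an ROI and each punctum's signed
#' distance to the perimeter is recorded, so annulus membership at any
#' expansion is known geometry. \code{"colocal"}: two spot channels with
#' a planted number of coincident pairs plus singletons in each channel.
#'
#' @param gp \code{\link{GroupParams}} (puncta density).
#' @param kind one of "cfos", "puncta", "colocal".
#' @param seed integer seed.
#' @param punctumDiameter punctum diameter (um); rejected when < 2 px.
#' @param nPositive,nNegative planted counts for \code{kind = "cfos"}.
#' @param nPairs,nSingle planted counts for \code{kind = "colocal"}.
#' @return list with \code{image} (\linkS4class{LabeledImage}) and
#'   \code{roi} (\linkS4class{RoiSet}); ground truth in
#'   \code{groundTruth(image)}.
#' @export
genImages <- function(gp, kind = c("puncta", "cfos", "colocal"), seed = 1,
                      punctumDiameter = 0.6, nPositive = 15,
                      nNegative = 10, nPairs = 10, nSingle = 5) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    puncta = genPunctaImage(gp, punctumDiameter),
    cfos = genCfosImage(nPositive, nNegative),
    colocal = genColocalImage(nPairs, nSingle))
}

genPunctaImage <- function(gp, punctumDiameter) {
  px <- 0.1                                  # um per pixel
  stopIfNot(punctumDiameter / px >= 2,
            "punctum diameter below 2 px is unresolvable")
  side <- 320L                               # 32 x 32 um field
  bg <- 100
  somaR <- 6                                 # um
  cxUm <- 16; cyUm <- 16
  poly <- circlePolygon(cxUm, cyUm, somaR, n = 96)
  img <- matrix(bg, side, side)
  # darker soma interior (cell body largely devoid of immunofluorescence)
  xs <- ((1:side) - 0.5) * px
  dd <- outer(xs, xs, function(yy, xx)
    sqrt((xx - cxUm)^2 + (yy - cyUm)^2))
  img[dd < somaR - 0.3] <- 60
  perim <- polygonPerimeter(poly)
  nIn <- max(0L, round(gp$punctaDensity * perim))
  # planted in-annulus puncta: radial offsets within +/-0.8 um of the
  # perimeter; distractors planted deep inside and far outside
  thIn <- stats::runif(nIn, 0, 2 * pi)
  rIn <- somaR + stats::runif(nIn, -0.8, 0.8)
  nDeep <- 3L; nFar <- 4L
  thD <- stats::runif(nDeep, 0, 2 * pi); rD <- stats::runif(nDeep, 0.5, 2)
  thF <- stats::runif(nFar, 0, 2 * pi)
  rF <- somaR + stats::runif(nFar, 3.5, 6)
  th <- c(thIn, thD, thF); rr <- c(rIn, rD, rF)
  pxX <- (cxUm + rr * cos(th)) / px + 0.5
  pxY <- (cyUm + rr * sin(th)) / px + 0.5
  keep <- pxX > 4 & pxX < side - 3 & pxY > 4 & pxY < side - 3
  # enforce separation so puncta never merge under labeling
  sel <- which(keep)
  chosen <- integer()
  for (i in sel) {
    if (!length(chosen) || all((pxX[chosen] - pxX[i])^2 +
                               (pxY[chosen] - pxY[i])^2 >=
                               (1.4 / px)^2))
      chosen <- c(chosen, i)
  }
  sigma <- punctumDiameter / 2.355 / px      # FWHM -> sd, px
  img <- renderBlobs(img, pxX[chosen], pxY[chosen],
                     rep(sigma, length(chosen)), rep(4000, length(chosen)))
  img <- img + matrix(stats::rnorm(side^2, 0, 5), side, side)
  img[img < 0] <- 0
  radOff <- rr[chosen] - somaR               # signed dist to perimeter, um
  gt <- data.frame(x = pxX[chosen] * px, y = pxY[chosen] * px,
                   radialOffset = radOff,
                   planted = rep(c("annulus", "deep", "far"),
                                 c(nIn, nDeep, nFar))[chosen])
  image <- LabeledImage(list(puncta = img), pixelSize = px,
    meta = list(groundTruth = list(puncta = gt, somaRadius = somaR,
      somaCenter = c(cxUm, cyUm), background = 100,
      nInAnnulus = sum(abs(gt$radialOffset) <= 1.4))))
  list(image = image, roi = RoiSet(list(poly),
    meta = list(perimeter = perim)))
}

genCfosImage <- function(nPositive, nNegative) {
  px <- 0.5
  side <- 256L
  bg <- 100
  n <- nPositive + nNegative
  pts <- placeSeparated(n, 16, side - 16, minSep = 24)
  nPl <- nrow(pts)
  nPos <- min(nPositive, nPl)
  peaks <- c(stats::runif(nPos, 320, 520),
             stats::runif(nPl - nPos, 60, 140))
  img <- matrix(bg, side, side)
  img <- renderDisks(img, pts[, 1], pts[, 2],
                     radiusPx = rep(4 / px, nPl), edgePx = 1, peaks)
  img <- img + matrix(stats::rnorm(side^2, 0, 4), side, side)
  img[img < 0] <- 0
  gt <- data.frame(x = pts[, 1] * px, y = pts[, 2] * px,
                   peak = peaks, positive = peaks + bg > 3 * bg)
  image <- LabeledImage(list(cfos = img), pixelSize = px,
    meta = list(groundTruth = list(nuclei = gt, background = bg,
      nPositive = sum(gt$positive))))
  list(image = image, roi = RoiSet(list(), meta = list()))
}

genColocalImage <- function(nPairs, nSingle) {
  px <- 0.5
  side <- 256L
  bg <- 50
  nTot <- nPairs + 2 * nSingle
  pts <- placeSeparated(nTot, 16, side - 16, minSep = 20)
  stopIfNot(nrow(pts) == nTot, "could not place the requested spots")
  sig <- 2 / 2.355 / px
  a <- pts[seq_len(nPairs + nSingle), , drop = FALSE]
  b <- rbind(pts[seq_len(nPairs), , drop = FALSE],
             pts[(nPairs + nSingle + 1):nTot, , drop = FALSE])
  chA <- renderBlobs(matrix(bg, side, side), a[, 1], a[, 2],
                     rep(sig, nrow(a)), rep(500, nrow(a)))
  chB <- renderBlobs(matrix(bg, side, side), b[, 1], b[, 2],
                     rep(sig, nrow(b)), rep(500, nrow(b)))
  image <- LabeledImage(list(a = chA, b = chB), pixelSize = px,
    meta = list(groundTruth = list(
      aCentroids = a * px, bCentroids = b * px,
      nDouble = as.integer(nPairs), background = bg)))
  list(image = image, roi = RoiSet(list(), meta = list()))
}
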