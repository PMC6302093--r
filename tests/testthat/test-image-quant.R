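# Rule-based image quantification.

test_that("cFos counting follows the 3x-background rule exactly", {
  img <- LabeledImage(matrix(100, 128, 128), pixelSize = 0.5)
  expect_identical(countCfos(img, background = 100)$n, 0L)
  gen <- genImages(GroupParams(), "cfos", seed = 2)
  gt <- groundTruth(gen$image)
  res <- countCfos(gen$image, background = gt$background)
  expect_identical(res$n, gt$nPositive)
  # a nucleus peaking below 3x background is not counted
  lone <- AmygQuant:::renderDisks(matrix(100, 128, 128), 64, 64,
                                  radiusPx = 8, edgePx = 1, peak = 150)
  expect_identical(countCfos(LabeledImage(lone, 0.5),
                             background = 100)$n, 0L)
  hot <- AmygQuant:::renderDisks(matrix(100, 128, 128), 64, 64,
                                 radiusPx = 8, edgePx = 1, peak = 350)
  expect_identical(countCfos(LabeledImage(hot, 0.5),
                             background = 100)$n, 1L)
  sat <- LabeledImage(matrix(1000, 64, 64), pixelSize = 0.5)
  expect_warning(rs <- countCfos(sat, background = 100), "saturated")
  expect_false(rs$usable)
})

test_that("threshold monotonicity: higher threshold never adds components", {
  gen <- genImages(GroupParams(), "cfos", seed = 9)
  m <- getChannel(gen$image, 1)
  px <- pixelSize(gen$image)
  ns <- vapply(c(200, 300, 400, 520), function(th)
    nrow(AmygQuant:::labelComponents(m, th, px, 20, 300)), integer(1))
  # area gating can drop but never gain components as threshold rises
  expect_true(all(diff(vapply(c(200, 300, 400, 520), function(th) {
    bw <- EBImage::bwlabel(m > th); max(bw)
  }, numeric(1))) <= 0))
})

test_that("colocalization counts planted coincident pairs", {
  a <- data.frame(x = c(1, 5, 9), y = c(1, 5, 9))
  expect_identical(colocalizeSpots(a, a, radius = 0.5)$n, 3L)
  b <- data.frame(x = a$x + 10, y = a$y)
  expect_identical(colocalizeSpots(a, b, radius = 2)$n, 0L)
  expect_error(colocalizeSpots(a, b, radius = -1), ">= 0")
  gen <- genImages(GroupParams(), "colocal", seed = 4)
  gt <- groundTruth(gen$image)
  ca <- countCfos(gen$image, background = gt$background, channel = "a",
                  minArea = 2, maxArea = 100)
  cb <- countCfos(gen$image, background = gt$background, channel = "b",
                  minArea = 2, maxArea = 100)
  expect_identical(colocalizeSpots(ca$centroids, cb$centroids,
                                   radius = 2)$n, gt$nDouble)
})

test_that("perisomatic puncta: planted annulus counts and density", {
  gen <- genImages(GroupParams(punctaDensity = 0.25), "puncta", seed = 3)
  gt <- groundTruth(gen$image)
  res <- perisomaticPuncta(gen$image, gen$roi, expansion = 1.4,
                           threshold = 3 * gt$background)
  expect_identical(res$nPuncta, gt$nInAnnulus)
  expect_equal(res$perimeter, 2 * pi * gt$somaRadius, tolerance = 0.01)
  expect_equal(res$density, res$nPuncta / res$perimeter)
  # zero planted puncta -> zero counted
  gen0 <- genImages(GroupParams(punctaDensity = 0), "puncta", seed = 5)
  res0 <- perisomaticPuncta(gen0$image, gen0$roi, expansion = 1.4,
    threshold = 3 * groundTruth(gen0$image)$background)
  # distractors exist but none inside the annulus
  expect_identical(res0$nPuncta, groundTruth(gen0$image)$nInAnnulus)
  # punctum 4 um outside the perimeter is excluded at 1.4 um expansion
  far <- gt$puncta[gt$puncta$planted == "far", ]
  expect_true(all(far$radialOffset > 1.4))
  # a polygon leaving the image is skipped with a warning
  offPoly <- AmygQuant:::circlePolygon(1, 1, 2, 24)
  expect_warning(rs <- perisomaticPuncta(gen$image,
    RoiSet(list(offPoly)), expansion = 1.4,
    threshold = 3 * gt$background), "skipped")
  expect_true(rs$skipped)
})

test_that("counts and densities are invariant under 90-degree rotation", {
  gen <- genImages(GroupParams(), "puncta", seed = 7)
  gt <- groundTruth(gen$image)
  m <- getChannel(gen$image, 1)
  px <- pixelSize(gen$image)
  rot <- t(m)[ncol(m):1, ]                      # 90 deg rotation
  lim <- nrow(m) * px
  poly <- polygons(gen$roi)[[1]]
  polyRot <- cbind(poly[, 2], lim - poly[, 1])
  r1 <- perisomaticPuncta(gen$image, gen$roi, 1.4,
                          threshold = 3 * gt$background)
  r2 <- perisomaticPuncta(LabeledImage(rot, px),
                          RoiSet(list(polyRot)), 1.4,
                          threshold = 3 * gt$background)
  expect_identical(r1$nPuncta, r2$nPuncta)
  expect_equal(r1$perimeter, r2$perimeter, tolerance = 1e-9)
})

test_that("rasterized annulus area matches 4*pi*r*d geometry", {
  poly <- AmygQuant:::circlePolygon(16, 16, 6, 128)
  mask <- annulusMask(c(320, 320), 0.1, poly, 1.4)
  area <- sum(mask) * 0.1^2
  expect_equal(area, 4 * pi * 6 * 1.4, tolerance = 0.02 * 4 * pi * 6 * 1.4)
})
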