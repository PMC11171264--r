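test_that("principal axes of a 2:1 rectangle grid are axis-aligned with 4:1 variance", {
  u <- seq(0, 1, length.out = 11)
  pts <- as.matrix(expand.grid(x = 2 * u, y = u))
  pa <- principalAxes(pts)
  expect_equal(abs(pa$axes[, 1]), c(1, 0), tolerance = 1e-10)
  expect_equal(pa$variances[1] / pa$variances[2], 4, tolerance = 1e-10)
})

test_that("principal axes rotate with the points and stay orthonormal", {
  u <- seq(0, 1, length.out = 11)
  pts <- as.matrix(expand.grid(x = 2 * u, y = u))
  rot <- rotatePoints(pts, 30)
  pa <- principalAxes(rot)
  expected <- c(cos(pi / 6), sin(pi / 6))
  expect_lt(min(sum((pa$axes[, 1] - expected)^2),
                sum((pa$axes[, 1] + expected)^2)), 1e-20)
  set.seed(4)
  rnd <- matrix(rnorm(40), ncol = 2)
  ax <- principalAxes(rnd)$axes
  expect_lt(max(abs(t(ax) %*% ax - diag(2))), 1e-10)
})

test_that("collinear points are rejected", {
  expect_error(principalAxes(cbind(1:10, 2 * (1:10) + 3)),
               class = "melbands_geometry_error")
})

test_that("estimated thickness of a rectangle slide is exact and rotation-invariant", {
  ann <- rectAnnotation(depthUm = 3000, widthUm = 6000)
  th <- estimateThickness(ann)
  expect_equal(th$thicknessUm, 3000, tolerance = 1e-9)
  expect_equal(abs(th$depthAxis), c(0, 1), tolerance = 1e-9)
  rot <- rotateAnnotation(ann, 45, center = c(3000, 1500))
  thr <- estimateThickness(rot)
  expect_lt(abs(thr$thicknessUm - 3000) / 3000, 0.01)
})

test_that("degenerate annotations are rejected", {
  sliver <- rectAnnotation(depthUm = 1, widthUm = 6000)
  expect_error(partitionBands(sliver), class = "melbands_geometry_error")
  inside <- rectAnnotation()
  inside$epidermis <- cbind(c(2000, 4000, 4000, 2000), c(1000, 1000, 2000, 2000))
  expect_error(estimateThickness(inside), class = "melbands_geometry_error")
})

test_that("rectangle tumor partitions into three equal bands covering the polygon", {
  ann <- rectAnnotation(depthUm = 3000, widthUm = 6000)
  geom <- partitionBands(ann, resolution = 10)
  areas <- bandAreas(geom)
  total <- sum(areas)
  expect_true(all(abs(areas - total / 3) / (total / 3) < 0.01))
  expect_lt(abs(total - geom@tumorAreaMm2) / geom@tumorAreaMm2, 0.005)
  # every in-tumor pixel is in exactly one band
  br <- geom@bandRaster
  dr <- geom@depthRaster
  expect_identical(is.na(br), is.na(dr))
  expect_true(all(br[!is.na(br)] %in% 1:3))
  expect_equal(thicknessMm(geom), 3)
})

test_that("halving the raster resolution changes band areas by under 0.5%", {
  # rotated slide: pixel rows decorrelate from the depth contours, so this
  # probes genuine raster convergence rather than aligned-grid coincidence
  ann <- rotateAnnotation(rectAnnotation(depthUm = 2000, widthUm = 3000),
                          20, center = c(1500, 1000))
  a10 <- bandAreas(partitionBands(ann, resolution = 10))
  a5 <- bandAreas(partitionBands(ann, resolution = 5))
  expect_true(all(abs(a10 - a5) / a5 < 0.005))
})

test_that("the invasive margin of a rectangle is its deep edge", {
  ann <- rectAnnotation(depthUm = 3000, widthUm = 6000)
  geom <- partitionBands(ann, resolution = 10)
  mar <- invasiveMargin(geom)
  expect_gt(nrow(mar), 10)
  # all margin points lie on the bottom edge, spanning the width
  expect_true(all(abs(mar[, 2] - 3000) < 1e-6))
  len <- sum(sqrt(rowSums(diff(mar)^2)))
  expect_lt(abs(len - 6000) / 6000, 0.02)
  # contract: margin depth >= 2T/3
  dep <- melbands:::distToPolyline(mar, geom@superficialBoundary)
  expect_true(all(dep >= geom@cutoffsUm[2] - 1e-6))
})

test_that("band structure is equivariant under rigid rotation", {
  ann <- rectAnnotation(depthUm = 2000, widthUm = 3000)
  geom <- partitionBands(ann, resolution = 10)
  ctr <- c(1500, 1000)
  rot <- rotateAnnotation(ann, 30, center = ctr)
  geomR <- partitionBands(rot, resolution = 10)
  expect_lt(abs(geomR@thicknessUm - geom@thicknessUm) / geom@thicknessUm, 0.01)
  aR <- bandAreas(geomR); a <- bandAreas(geom)
  expect_true(all(abs(aR - a) / a < 0.01))
  # cells rotate with the slide and keep their labels (raster tolerance)
  set.seed(8)
  cells <- data.frame(centroid_x_um = runif(800, 0, 3000),
                      centroid_y_um = runif(800, 0, 2000))
  lab <- annotateCells(cells, geom)$band
  rc <- rotatePoints(as.matrix(cells), 30, center = ctr)
  labR <- annotateCells(data.frame(centroid_x_um = rc[, 1],
                                   centroid_y_um = rc[, 2]), geomR)$band
  expect_gt(mean(as.character(lab) == as.character(labR)), 0.98)
  # the margin rotates rigidly: rotated original margin sits on the new one
  marBack <- rotatePoints(invasiveMargin(geom), 30, center = ctr)
  d <- melbands:::distToPolyline(marBack, invasiveMargin(geomR))
  expect_lt(stats::median(d), 20)
})

test_that("cells are assigned bands by half-open depth intervals", {
  ann <- rectAnnotation(depthUm = 3000, widthUm = 6000)
  geom <- partitionBands(ann, resolution = 10)
  cells <- data.frame(
    centroid_x_um = c(3000, 3000, 3000, 3000, 9000),
    centroid_y_um = c(100, 1500, 2900, 1005, 100))
  out <- annotateCells(cells, geom)
  expect_equal(as.character(out$band),
               c("superficial", "middle", "invasive", "middle", "outside"))
  # row 4 sits in the pixel whose raster depth is exactly T/3 = 1000
  expect_equal(out$depth_um[4], 1000)
  expect_true(is.na(out$depth_um[5]))
  expect_true(all(out$dist_to_margin_um[1:4] > 0))
})

test_that("uniform cells distribute over bands in proportion to band areas", {
  sim <- simulateSlide(slideSimConfig(seed = 13))
  geom <- partitionBands(sim$annotation, resolution = 10)
  cells <- annotateCells(sim$cells, geom)
  counts <- table(factor(cells$band, levels = c("superficial", "middle", "invasive")))
  pr <- bandAreas(geom) / sum(bandAreas(geom))
  pv <- chisq.test(as.numeric(counts), p = as.numeric(pr))$p.value
  expect_gt(pv, 0.001)
})
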