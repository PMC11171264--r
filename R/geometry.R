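#' Principal axes of a 2-D point set
#'
#' Eigen-decomposition of the centred covariance matrix, axes sorted by
#' descending variance. Axis signs are made deterministic; when a `reference`
#' direction is supplied (typically epidermis centroid to tumor centroid) the
#' second axis is flipped to have positive component along it.
#'
#' @param points two-column matrix of coordinates.
#' @param reference optional 2-vector fixing the sign of the second axis.
#' @return list with `axes` (2x2 matrix, axes in columns) and `variances`
#'   (length 2, descending).
#' @export
principalAxes <- function(points, reference = NULL) {
  pts <- as.matrix(points)
  if (nrow(pts) < 3L)
    mbGeometryError("principal axes need at least 3 points")
  cv <- stats::cov(pts)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] <= 1e-12 * max(eg$values[1], 1))
    mbGeometryError("points are collinear; principal axes are degenerate")
  axes <- eg$vectors
  # deterministic signs: largest-magnitude component positive
  for (j in 1:2) {
    k <- which.max(abs(axes[, j]))
    if (axes[k, j] < 0) axes[, j] <- -axes[, j]
  }
  if (!is.null(reference) && sum(axes[, 2] * reference) < 0)
    axes[, 2] <- -axes[, 2]
  list(axes = axes, variances = eg$values)
}

#' Estimate tumor thickness and depth axis from a slide annotation
#'
#' The tumor boundary is resampled at uniform arc length and its principal
#' axes computed. The depth axis is the principal axis most aligned with the
#' direction from the epidermis centroid to the tumor centroid, oriented to
#' point into the tumor. The estimated thickness is the extent of the
#' boundary's projection onto that axis — the longest distance from the
#' epidermis-facing edge to the deepest part of the tumor. The origin is the
#' boundary point with minimal depth projection.
#'
#' @param annotation a slide annotation as returned by [readAnnotation()] or
#'   [simulateSlide()]: a list with `tumor` and `epidermis` polygon matrices
#'   (µm) and a `slide_id`.
#' @param boundarySpacing arc-length spacing (µm) for boundary resampling.
#' @return list with `depthAxis` (unit 2-vector), `origin` (2-vector),
#'   `thicknessUm`, and `boundary` (the resampled boundary points).
#' @export
estimateThickness <- function(annotation, boundarySpacing = 20) {
  tum <- as.matrix(annotation$tumor)
  epi <- as.matrix(annotation$epidermis)
  tumC <- polygonCentroid(tum)
  epiC <- polygonCentroid(epi)
  if (pointsInPolygon(rbind(epiC), tum))
    mbGeometryError("epidermis centroid lies inside the tumor polygon")
  bnd <- densifyBoundary(tum, boundarySpacing)
  pa <- principalAxes(bnd, reference = tumC - epiC)
  dir <- tumC - epiC
  dots <- abs(t(pa$axes) %*% dir)
  ax <- pa$axes[, which.max(dots)]
  if (sum(ax * dir) < 0) ax <- -ax
  proj <- bnd %*% ax
  thick <- max(proj) - min(proj)
  list(depthAxis = as.numeric(ax),
       origin = as.numeric(bnd[which.min(proj), ]),
       thicknessUm = as.numeric(thick),
       boundary = bnd)
}

#' Partition a tumor annotation into superficial, middle and invasive bands
#'
#' Builds the full per-slide spatial model. The superficial tumor boundary —
#' the portion within `superficialGapUm` of the epidermis polygon — seeds a
#' Euclidean distance transform over a raster of the tumor polygon; per-pixel
#' depth is distance to that boundary. Depth cutoffs are proportional thirds
#' of the PCA estimated thickness T: pixels at depth [0, T/3) are superficial,
#' [T/3, 2T/3) middle, and [2T/3, Inf) invasive (half-open, lower-inclusive;
#' pixels deeper than T — possible because raster depth is geodesic-free
#' Euclidean distance while T is an axis projection — stay invasive). The
#' invasive margin is the deep-facing part of the tumor boundary at depth at
#' least 2T/3 (outward normal component along the depth axis above 0.25),
#' i.e. the part of the melanoma opposite the epidermis.
#'
#' @param annotation slide annotation (see [estimateThickness()]).
#' @param resolution raster resolution, µm per pixel (default 10).
#' @param superficialGapUm maximum distance from the epidermis polygon for a
#'   tumor boundary point to count as superficial (default 50 µm).
#' @param depthInfo optional precomputed result of [estimateThickness()].
#' @return A [BandGeometry-class].
#' @export
partitionBands <- function(annotation, resolution = 10, superficialGapUm = 50,
                           depthInfo = NULL) {
  if (resolution <= 0) mbConfigError("raster resolution must be positive")
  if (is.null(depthInfo))
    depthInfo <- estimateThickness(annotation,
                                   boundarySpacing = min(20, resolution))
  Tum <- depthInfo$thicknessUm
  if (!is.finite(Tum) || Tum <= 2 * resolution)
    mbGeometryError("estimated thickness (%.3g um) too small to band at %.3g um resolution",
                    Tum, resolution)
  tum <- as.matrix(annotation$tumor)
  epi <- as.matrix(annotation$epidermis)
  bnd <- densifyBoundary(tum, min(resolution / 2, 20))

  # superficial boundary: boundary points adjacent to the epidermis
  dEpi <- distToPolyline(bnd, epi, closed = TRUE)
  supIdx <- dEpi <= superficialGapUm
  if (!any(supIdx)) {
    proj <- as.numeric(bnd %*% depthInfo$depthAxis)
    supIdx <- proj <= stats::quantile(proj, 0.1)
  }
  supBnd <- bnd[supIdx, , drop = FALSE]

  # raster of the tumor polygon
  xr <- range(tum[, 1]); yr <- range(tum[, 2])
  xs <- seq(xr[1] + resolution / 2, xr[2], by = resolution)
  ys <- seq(yr[1] + resolution / 2, yr[2], by = resolution)
  if (!length(xs) || !length(ys))
    mbGeometryError("tumor polygon rasterises to zero pixels at %.3g um", resolution)
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  inside <- pointsInPolygon(grid, tum)
  if (!any(inside))
    mbGeometryError("tumor polygon rasterises to zero interior pixels at %.3g um",
                    resolution)
  nx <- length(xs); ny <- length(ys)

  # distance transform from the superficial boundary (seed pixels = 0)
  seedI <- pmin(pmax(round((supBnd[, 1] - xs[1]) / resolution) + 1L, 1L), nx)
  seedJ <- pmin(pmax(round((supBnd[, 2] - ys[1]) / resolution) + 1L, 1L), ny)
  m <- matrix(1, nx, ny)
  m[cbind(seedI, seedJ)] <- 0
  depthPx <- EBImage::distmap(m)
  depth <- matrix(as.numeric(depthPx) * resolution, nx, ny)
  insideM <- matrix(inside, nx, ny)
  depth[!insideM] <- NA_real_

  cut1 <- Tum / 3; cut2 <- 2 * Tum / 3
  band <- matrix(NA_integer_, nx, ny)
  band[insideM] <- ifelse(depth[insideM] < cut1, 1L,
                          ifelse(depth[insideM] < cut2, 2L, 3L))
  counts <- tabulate(band[!is.na(band)], nbins = 3L)
  areas <- counts * resolution^2 / 1e6
  names(areas) <- c("superficial", "middle", "invasive")
  if (any(areas == 0))
    mbGeometryError("band(s) with zero area: %s",
                    paste(names(areas)[areas == 0], collapse = ", "))

  # invasive margin: deep-facing boundary at depth >= 2T/3
  bndDepth <- distToPolyline(bnd, supBnd, closed = FALSE)
  nB <- nrow(bnd)
  nxt <- c(2:nB, 1L); prv <- c(nB, 1:(nB - 1L))
  tang <- bnd[nxt, ] - bnd[prv, ]
  tl <- sqrt(rowSums(tang^2)); tl[tl == 0] <- 1
  tang <- tang / tl
  sArea <- sum(bnd[, 1] * bnd[nxt, 2] - bnd[nxt, 1] * bnd[, 2]) / 2
  normal <- if (sArea > 0) cbind(tang[, 2], -tang[, 1]) else cbind(-tang[, 2], tang[, 1])
  facing <- as.numeric(normal %*% depthInfo$depthAxis)
  mIdx <- which(bndDepth >= cut2 & facing > 0.25)
  margin <- if (length(mIdx)) {
    # reorder so the polyline is contiguous along the ring
    gaps <- diff(c(mIdx, mIdx[1] + nB))
    br <- which.max(gaps)
    if (gaps[br] > 1L && br < length(mIdx))
      mIdx <- c(mIdx[(br + 1):length(mIdx)], mIdx[seq_len(br)])
    bnd[mIdx, , drop = FALSE]
  } else {
    warning("no invasive margin found (no deep-facing boundary at depth >= 2T/3)")
    matrix(numeric(0), 0, 2)
  }

  new("BandGeometry",
      slideId = as.character(annotation$slide_id %||% "slide"),
      depthAxis = depthInfo$depthAxis, origin = depthInfo$origin,
      thicknessUm = Tum, cutoffsUm = c(cut1, cut2),
      rasterRes = resolution, rasterOrigin = c(xs[1], ys[1]),
      depthRaster = depth, bandRaster = band,
      bandAreasMm2 = areas, tumorAreaMm2 = polygonAreaUm2(tum) / 1e6,
      margin = margin, superficialBoundary = supBnd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Annotate cells with band membership, depth and distance to invasive margin
#'
#' Each cell is mapped to its raster pixel; cells whose pixel falls outside
#' the tumor polygon get band `"outside"` and missing depth/distance. In-tumor
#' cells get the pixel's distance-transform depth, the half-open thirds band
#' label, and the Euclidean distance to the invasive-margin polyline.
#'
#' @param cells data.frame with `centroid_x_um`, `centroid_y_um`.
#' @param geometry a [BandGeometry-class] in the same coordinate frame.
#' @return `cells` with columns `band` (factor: superficial, middle, invasive,
#'   outside), `depth_um`, `dist_to_margin_um` added or overwritten.
#' @export
annotateCells <- function(cells, geometry) {
  stopifnot(is(geometry, "BandGeometry"))
  lvl <- c("superficial", "middle", "invasive", "outside")
  n <- nrow(cells)
  if (n == 0L) {
    cells$band <- factor(character(0), levels = lvl)
    cells$depth_um <- numeric(0)
    cells$dist_to_margin_um <- numeric(0)
    return(cells)
  }
  res <- geometry@rasterRes
  org <- geometry@rasterOrigin
  nx <- nrow(geometry@bandRaster); ny <- ncol(geometry@bandRaster)
  i <- round((cells$centroid_x_um - org[1]) / res) + 1L
  j <- round((cells$centroid_y_um - org[2]) / res) + 1L
  ok <- i >= 1L & i <= nx & j >= 1L & j <= ny
  bandIdx <- rep(NA_integer_, n)
  depth <- rep(NA_real_, n)
  idx <- cbind(pmax(pmin(i, nx), 1L), pmax(pmin(j, ny), 1L))
  bandIdx[ok] <- geometry@bandRaster[idx[ok, , drop = FALSE]]
  depth[ok] <- geometry@depthRaster[idx[ok, , drop = FALSE]]
  band <- factor(ifelse(is.na(bandIdx), "outside", lvl[bandIdx]), levels = lvl)
  dist <- rep(NA_real_, n)
  inT <- band != "outside"
  if (nrow(geometry@margin) && any(inT)) {
    dist[inT] <- distToPolyline(
      cbind(cells$centroid_x_um[inT], cells$centroid_y_um[inT]),
      geometry@margin)
  }
  cells$band <- band
  cells$depth_um <- depth
  cells$dist_to_margin_um <- dist
  cells
}
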