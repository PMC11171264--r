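# Internal helpers: classed conditions and small planar-geometry primitives.

mbStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "melbands_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))))
}

mbConfigError     <- function(msg, ...) mbStop("melbands_config_error", msg, ...)
mbFormatError     <- function(msg, ...) mbStop("melbands_format_error", msg, ...)
mbValidationError <- function(msg, ...) mbStop("melbands_validation_error", msg, ...)
mbDegenerateError <- function(msg, ...) mbStop("melbands_degenerate_error", msg, ...)
mbGeometryError   <- function(msg, ...) mbStop("melbands_geometry_error", msg, ...)
mbGatingError     <- function(msg, ...) mbStop("melbands_gating_error", msg, ...)

# Ensure a polygon matrix is closed (first vertex repeated last).
closeRing <- function(poly) {
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  poly
}

# Ensure an open ring (no repeated last vertex).
openRing <- function(poly) {
  if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  poly
}

polygonAreaUm2 <- function(poly) {
  poly <- openRing(as.matrix(poly))
  abs(pracma::polyarea(poly[, 1], poly[, 2]))
}

polygonCentroid <- function(poly) {
  poly <- openRing(as.matrix(poly))
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Resample a closed polygon boundary at (approximately) uniform arc-length
# spacing; returns a two-column matrix of points along the ring.
densifyBoundary <- function(poly, spacing) {
  ring <- closeRing(as.matrix(poly))
  segs <- diff(ring)
  lens <- sqrt(rowSums(segs^2))
  keep <- lens > 0
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    n <- max(1L, ceiling(lens[i] / spacing))
    tt <- (seq_len(n) - 1L) / n
    j <- j + 1L
    out[[j]] <- cbind(ring[i, 1] + tt * segs[i, 1],
                      ring[i, 2] + tt * segs[i, 2])
  }
  do.call(rbind, out)
}

# Minimum Euclidean distance from each point (n x 2) to a polyline given as an
# ordered set of vertices (m x 2). Vectorised over points per segment.
distToPolyline <- function(points, line, closed = FALSE) {
  pts <- as.matrix(points)
  ln <- as.matrix(line)
  if (closed) ln <- closeRing(ln)
  if (nrow(ln) == 1L) {
    return(sqrt((pts[, 1] - ln[1, 1])^2 + (pts[, 2] - ln[1, 2])^2))
  }
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(ln) - 1L)) {
    a <- ln[i, ]; b <- ln[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (pts[, 1] - (a[1] + t * ab[1]))^2 + (pts[, 2] - (a[2] + t * ab[2]))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

pointsInPolygon <- function(points, poly) {
  pts <- as.matrix(points)
  if (nrow(pts) == 0L) return(logical(0))
  mgcv::in.out(closeRing(as.matrix(poly)), pts)
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}
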