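#' Otsu threshold of a marker expression distribution
#'
#' Histogram-based Otsu split: the candidate thresholds are the interior bin
#' edges of a histogram with `nBins` bins spanning the 1st–99th percentile of
#' the values (values outside clamp into the end bins, so the split is robust
#' to isolated outliers). The chosen threshold maximises the between-class
#' variance
#' \deqn{\sigma_B^2(t) = \omega_0(t)\,\omega_1(t)\,[\mu_0(t) - \mu_1(t)]^2.}
#' When several consecutive edges attain the maximum exactly (a plateau, e.g.
#' with an empty gap between two spikes), the midpoint of the first and last
#' winning edges is reported.
#'
#' @param values numeric vector of non-negative intensities (at least two
#'   distinct values).
#' @param nBins number of histogram bins (default 256).
#' @return An [OtsuSplit-class]. Class probabilities and means are recomputed
#'   from the raw values split at the returned threshold.
#' @examples
#' sp <- otsuThreshold(c(rep(0, 500), rep(10, 500)))
#' sp@threshold  # 5, the plateau midpoint
#' @export
otsuThreshold <- function(values, nBins = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    mbDegenerateError("Otsu thresholding needs at least two distinct values")
  if (nBins < 2L) mbConfigError("nBins must be >= 2")
  qs <- stats::quantile(values, c(0.01, 0.99), names = FALSE, type = 7)
  lo <- qs[1]; hi <- qs[2]
  if (hi <= lo) { lo <- min(values); hi <- max(values) }
  edges <- seq(lo, hi, length.out = nBins + 1L)
  bin <- findInterval(values, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), nBins)          # clamp outliers into end bins
  counts <- tabulate(bin, nbins = nBins)
  centers <- (edges[-1L] + edges[-(nBins + 1L)]) / 2
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  m0 <- cumsum(p * centers)
  mTot <- m0[nBins]
  # candidate boundary after bin k = edge k+1, k in 1..nBins-1
  k <- seq_len(nBins - 1L)
  omega0 <- w0[k]; omega1 <- 1 - omega0
  valid <- omega0 > 0 & omega1 > 0
  sigmaB <- rep(-Inf, nBins - 1L)
  mu0 <- m0[k] / omega0
  mu1 <- (mTot - m0[k]) / omega1
  sigmaB[valid] <- (omega0 * omega1 * (mu0 - mu1)^2)[valid]
  mx <- max(sigmaB)
  win <- which(sigmaB >= mx * (1 - 1e-12) - 1e-300)
  tStar <- (edges[min(win) + 1L] + edges[max(win) + 1L]) / 2
  below <- values <= tStar
  w0r <- mean(below)
  new("OtsuSplit",
      threshold = tStar, omega0 = w0r, omega1 = 1 - w0r,
      mu0 = mean(values[below]), mu1 = mean(values[!below]),
      betweenVar = mx, nBins = as.integer(nBins), binRange = c(lo, hi))
}

#' Split values into background (T0) and foreground (T1) at an Otsu threshold
#'
#' @param values numeric vector.
#' @param otsu an [OtsuSplit-class] fitted on these (or comparable) values.
#' @return list with elements `background` (values <= threshold) and
#'   `foreground` (values > threshold). Only the foreground progresses to the
#'   mixture stage.
#' @export
splitForeground <- function(values, otsu) {
  stopifnot(is(otsu, "OtsuSplit"))
  below <- values <= otsu@threshold
  list(background = values[below], foreground = values[!below])
}

#' Fit a two-component Bayesian Gaussian mixture to log foreground intensities
#'
#' Models the natural log of the foreground (T1) intensities as a
#' two-component Gaussian mixture, fitted by MAP expectation–maximisation with
#' a symmetric Dirichlet(1) prior on the weights and weak, data-centred
#' normal–inverse-gamma priors on the component means and variances. The
#' priors regularise against collapsing components while leaving the fit
#' essentially maximum-likelihood; the penalised log-likelihood trace is
#' monotonically non-decreasing. Initialisation is deterministic: the log
#' values are split at their median and component moments computed from the
#' two halves, so repeated fits are identical.
#'
#' @param t1Values positive foreground intensities (linear scale), length >= 10.
#' @param maxIter maximum EM iterations (default 3000).
#' @param tol convergence tolerance on the objective change (default 1e-6).
#' @return A [LogMixture-class] with components sorted by mean.
#' @export
fitLogMixture <- function(t1Values, maxIter = 3000L, tol = 1e-6) {
  t1Values <- t1Values[is.finite(t1Values) & t1Values > 0]
  if (length(t1Values) < 10L)
    mbGatingError("need at least 10 positive foreground values to fit the mixture")
  x <- log(t1Values)
  n <- length(x)
  vx <- stats::var(x)
  if (vx < .Machine$double.eps)
    mbDegenerateError("foreground values have zero variance on the log scale")

  # weak data-centred NIG priors; Dirichlet(1) weight prior adds no pseudo-counts
  m0 <- mean(x); kappa0 <- 1e-3
  a0 <- 1e-3; b0 <- 1e-3 * vx
  varFloor <- 1e-10 * vx

  med <- stats::median(x)
  grp <- x > med
  if (all(grp) || !any(grp)) grp <- x > m0
  mu <- c(mean(x[!grp]), mean(x[grp]))
  s2 <- c(stats::var(x[!grp]), stats::var(x[grp]))
  s2[!is.finite(s2) | s2 < varFloor] <- vx
  pi2 <- mean(grp); w <- c(1 - pi2, pi2)

  logPrior <- function(mu, s2) {
    sum(-0.5 * log(s2) - kappa0 * (mu - m0)^2 / (2 * s2) -
        (a0 + 1) * log(s2) - b0 / s2)
  }
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  prev <- -Inf
  while (iter < maxIter) {
    iter <- iter + 1L
    ld <- cbind(log(w[1]) + stats::dnorm(x, mu[1], sqrt(s2[1]), log = TRUE),
                log(w[2]) + stats::dnorm(x, mu[2], sqrt(s2[2]), log = TRUE))
    mrow <- pmax(ld[, 1], ld[, 2])
    lse <- mrow + log(exp(ld[, 1] - mrow) + exp(ld[, 2] - mrow))
    cur <- sum(lse) + logPrior(mu, s2)
    obj <- c(obj, cur)
    r2 <- exp(ld[, 2] - lse)
    r1 <- 1 - r2
    nk <- c(sum(r1), sum(r2))
    w <- nk / n
    xb <- c(if (nk[1] > 0) sum(r1 * x) / nk[1] else m0,
            if (nk[2] > 0) sum(r2 * x) / nk[2] else m0)
    mu <- (kappa0 * m0 + nk * xb) / (kappa0 + nk)
    sk <- c(sum(r1 * (x - mu[1])^2), sum(r2 * (x - mu[2])^2))
    s2 <- (sk + kappa0 * (mu - m0)^2 + 2 * b0) / (nk + 2 * a0 + 3)
    s2 <- pmax(s2, varFloor)
    if (is.finite(prev) && abs(cur - prev) < tol) { converged <- TRUE; break }
    prev <- cur
  }
  ord <- order(mu)
  new("LogMixture",
      weights = w[ord], means = mu[ord], sds = sqrt(s2[ord]),
      nIter = iter, converged = converged, objective = obj)
}

#' Weighted-density intersection of a two-component log mixture
#'
#' Solves \eqn{\pi_1 N(x\mid\mu_1,\sigma_1) = \pi_2 N(x\mid\mu_2,\sigma_2)} for
#' the root in the open interval \eqn{(\mu_1, \mu_2)}. Taking logs turns the
#' equation into a quadratic in x (linear when \eqn{\sigma_1 = \sigma_2}).
#' When no root lies inside the interval (extreme weight imbalance), the point
#' in \eqn{[\mu_1, \mu_2]} where the two weighted densities are closest is
#' returned instead and flagged.
#'
#' @param mix a [LogMixture-class] with distinct component means.
#' @return list with `logThreshold` (numeric, log-intensity scale) and
#'   `fallbackUsed` (logical).
#' @examples
#' mix <- new("LogMixture", weights = c(.5, .5), means = c(0, 4),
#'            sds = c(1, 1), nIter = 1L, converged = TRUE, objective = 0)
#' mixtureIntersection(mix)$logThreshold  # exactly 2
#' @export
mixtureIntersection <- function(mix) {
  stopifnot(is(mix, "LogMixture"))
  p <- mix@weights; mu <- mix@means; s <- mix@sds
  if (mu[2] - mu[1] < 1e-6)
    mbDegenerateError("component means coincide; no intersection threshold")
  K <- log(p[1] * s[2] / (p[2] * s[1]))
  a <- 1 / (2 * s[2]^2) - 1 / (2 * s[1]^2)
  b <- mu[1] / s[1]^2 - mu[2] / s[2]^2
  cc <- mu[2]^2 / (2 * s[2]^2) - mu[1]^2 / (2 * s[1]^2) + K
  roots <- if (abs(a) < 1e-12 * max(1 / s^2)) {
    if (b == 0) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside) >= 1L)
    return(list(logThreshold = inside[1], fallbackUsed = FALSE))
  # no intersection strictly between the means: closest weighted densities
  gap <- function(x) abs(p[1] * stats::dnorm(x, mu[1], s[1]) -
                         p[2] * stats::dnorm(x, mu[2], s[2]))
  grid <- seq(mu[1], mu[2], length.out = 1001L)
  g0 <- grid[which.min(gap(grid))]
  h <- (mu[2] - mu[1]) / 1000
  opt <- stats::optimize(gap, lower = max(mu[1], g0 - h), upper = min(mu[2], g0 + h))
  list(logThreshold = opt$minimum, fallbackUsed = TRUE)
}

# Construct a placeholder mixture for failed gates.
emptyLogMixture <- function() {
  new("LogMixture", weights = c(0.5, 0.5), means = c(0, 0), sds = c(1, 1),
      nIter = 0L, converged = FALSE, objective = numeric(0))
}

failedGate <- function(slideId, marker, compartment, nCells, reason) {
  emptyOtsu <- new("OtsuSplit", threshold = NA_real_, omega0 = 0.5, omega1 = 0.5,
                   mu0 = NA_real_, mu1 = NA_real_, betweenVar = NA_real_,
                   nBins = 0L, binRange = c(NA_real_, NA_real_))
  new("MarkerGate",
      slideId = slideId, marker = marker, compartment = compartment,
      otsu = emptyOtsu, mixture = emptyLogMixture(),
      logThreshold = NA_real_, finalThreshold = NA_real_,
      positiveComponent = NA_integer_, fallbackUsed = FALSE,
      foregroundUnimodal = FALSE,
      failed = TRUE, failureReason = reason,
      nCells = as.integer(nCells), nForeground = 0L,
      nDroppedNonpositive = 0L)
}

#' Gate one marker on one slide: full two-phase adaptive threshold
#'
#' Runs the whole per-slide chain on the configured compartment-mean column.
#' Fluorescence intensities are heavily right-skewed, and the whole chain
#' operates on their natural logarithm: the Otsu split into background (T0)
#' and foreground (T1) is computed on the log intensities (cells with
#' non-positive intensity are background outright), the two-component
#' Gaussian mixture is fitted to log(T1), and the final threshold sits at the
#' weighted density intersection. A cell is called positive iff its log
#' intensity lies in the foreground *and* at or above the intersection
#' threshold — i.e. on the higher-mean component's side. When the fitted
#' foreground mixture is not genuinely bimodal (Ashman's
#' \eqn{D = \sqrt{2}\,|\mu_2-\mu_1| / \sqrt{\sigma_1^2+\sigma_2^2} < 2}) the
#' two components describe a single population — refining inside it would
#' split the positive mode — so the Otsu boundary stands as the final
#' threshold and the whole foreground is positive. Any stage failure
#' (too few foreground cells, zero-variance foreground, coincident component
#' means) yields a failed gate with all cells called negative and the reason
#' recorded.
#'
#' @param cells data.frame of cell records (see [readCellTable()]); must carry
#'   the column `<marker>_<compartment>_mean`.
#' @param marker marker name, e.g. `"ki67"` or `"s100"`.
#' @param compartment compartment whose mean intensity is gated; defaults per
#'   marker via [defaultCompartment()].
#' @param nBins,maxIter,tol passed to [otsuThreshold()] / [fitLogMixture()].
#' @param slideId slide label recorded in the gate (defaults to the table's
#'   `slide_id` if present).
#' @return list with `gate` (a [MarkerGate-class]) and `positive` (logical
#'   vector, one entry per row of `cells`).
#' @export
gateMarker <- function(cells, marker, compartment = defaultCompartment(marker),
                       nBins = 256L, maxIter = 3000L, tol = 1e-6,
                       slideId = NULL) {
  if (is.null(slideId))
    slideId <- if ("slide_id" %in% names(cells) && nrow(cells))
      as.character(cells$slide_id[1]) else "slide"
  col <- paste(marker, compartment, "mean", sep = "_")
  if (nrow(cells) == 0L) {
    return(list(gate = failedGate(slideId, marker, compartment, 0L,
                                  "empty cell table"),
                positive = logical(0)))
  }
  if (!col %in% names(cells))
    mbFormatError("cell table lacks required intensity column '%s'", col)
  v <- cells[[col]]
  fail <- function(reason) {
    list(gate = failedGate(slideId, marker, compartment, nrow(cells), reason),
         positive = rep(FALSE, nrow(cells)))
  }
  nDropped <- sum(!is.finite(v) | v <= 0)
  lv <- log(v[is.finite(v) & v > 0])
  otsu <- tryCatch(otsuThreshold(lv, nBins = nBins),
                   melbands_error = function(e) e)
  if (inherits(otsu, "condition")) return(fail(conditionMessage(otsu)))
  inFg <- is.finite(v) & v > 0 & log(pmax(v, .Machine$double.xmin)) > otsu@threshold
  mix <- tryCatch(fitLogMixture(v[inFg], maxIter = maxIter, tol = tol),
                  melbands_error = function(e) e)
  if (inherits(mix, "condition")) return(fail(conditionMessage(mix)))
  if (mix@means[2] - mix@means[1] < 1e-6)
    return(fail("fitted component means coincide (unimodal foreground)"))
  # Ashman's D: are the two fitted components genuinely separated modes?
  ashmanD <- sqrt(2) * (mix@means[2] - mix@means[1]) / sqrt(sum(mix@sds^2))
  if (ashmanD < 2) {
    # one population: the Otsu boundary is the threshold, all of T1 positive
    logThr <- otsu@threshold
    fallback <- FALSE
    unimodal <- TRUE
  } else {
    its <- mixtureIntersection(mix)
    logThr <- its$logThreshold
    fallback <- its$fallbackUsed
    unimodal <- FALSE
  }
  positive <- inFg & log(pmax(v, .Machine$double.xmin)) >= logThr
  gate <- new("MarkerGate",
              slideId = slideId, marker = marker, compartment = compartment,
              otsu = otsu, mixture = mix,
              logThreshold = logThr,
              finalThreshold = exp(logThr),
              positiveComponent = 2L, fallbackUsed = fallback,
              foregroundUnimodal = unimodal,
              failed = FALSE, failureReason = "",
              nCells = nrow(cells), nForeground = as.integer(sum(inFg)),
              nDroppedNonpositive = as.integer(nDropped))
  list(gate = gate, positive = positive)
}

#' Default compartment whose mean intensity is gated for a marker
#'
#' Ki67 is a nuclear proliferation marker and is gated on the nucleus mean;
#' S100 is cytoplasmic in melanocytes and is gated on the cytoplasm mean;
#' anything else (e.g. DAPI) defaults to the nucleus mean. The mapping is
#' configuration, not biology baked into the gating code: any compartment can
#' be passed explicitly to [gateMarker()].
#'
#' @param marker marker name.
#' @return compartment name, one of "nucleus", "cytoplasm", "membrane".
#' @export
defaultCompartment <- function(marker) {
  switch(tolower(marker), s100 = "cytoplasm", "nucleus")
}
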