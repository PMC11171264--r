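# Independent oracles and small fixture builders shared across tests.

# Naive exhaustive Otsu: for every interior bin edge of a histogram with
# nBins bins over the 1st-99th percentile (outliers clamped into end bins),
# compute class probabilities and means from the histogram and the
# between-class variance directly; return the plateau-midpoint threshold.
otsuOracle <- function(values, nBins = 256L) {
  qs <- quantile(values, c(0.01, 0.99), names = FALSE, type = 7)
  lo <- qs[1]; hi <- qs[2]
  if (hi <= lo) { lo <- min(values); hi <- max(values) }
  edges <- seq(lo, hi, length.out = nBins + 1L)
  centers <- (edges[-1] + edges[-(nBins + 1)]) / 2
  b <- findInterval(values, edges, rightmost.closed = TRUE)
  b <- pmin(pmax(b, 1L), nBins)
  counts <- tabulate(b, nbins = nBins)
  n <- sum(counts)
  sig <- rep(-Inf, nBins - 1L)
  for (k in seq_len(nBins - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / n; w1 <- n1 / n
    m0 <- sum(counts[1:k] * centers[1:k]) / n0
    m1 <- sum(counts[(k + 1):nBins] * centers[(k + 1):nBins]) / n1
    sig[k] <- w0 * w1 * (m0 - m1)^2
  }
  mx <- max(sig)
  win <- which(sig >= mx * (1 - 1e-12) - 1e-300)
  (edges[min(win) + 1L] + edges[max(win) + 1L]) / 2
}

# Breslow-ties Cox log partial likelihood, written directly from the
# definition (single covariate or matrix).
breslowLogPL <- function(beta, time, event, x) {
  x <- as.matrix(x)
  eta <- as.numeric(x %*% beta)
  ll <- 0
  for (t in sort(unique(time[event]))) {
    d <- which(event & time == t)
    risk <- which(time >= t)
    ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[risk])))
  }
  ll
}

# Grid search + golden-section refinement of the single-covariate Breslow
# partial likelihood over beta in [-5, 5].
coxGridOracle <- function(time, event, x) {
  grid <- seq(-5, 5, by = 0.01)
  ll <- vapply(grid, breslowLogPL, numeric(1), time = time, event = event, x = x)
  b0 <- grid[which.max(ll)]
  optimize(function(b) breslowLogPL(b, time, event, x),
           lower = max(-5, b0 - 0.02), upper = min(5, b0 + 0.02),
           maximum = TRUE, tol = 1e-9)$maximum
}

# O(n^2) pair enumeration of Harrell's C: comparable pairs are those where
# the shorter time ends in an event; ties in score count half.
bruteForceC <- function(risk, time, event) {
  n <- length(risk)
  num <- den <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    s <- if (time[i] < time[j]) i else j  # shorter
    l <- if (time[i] < time[j]) j else i
    if (!event[s]) next
    den <- den + 1
    if (risk[s] > risk[l]) num <- num + 1
    else if (risk[s] == risk[l]) num <- num + 0.5
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Axis-aligned rectangular slide annotation: tumor depth x width (um) with an
# epidermis strip on the superficial (low-y) edge.
rectAnnotation <- function(depthUm = 3000, widthUm = 6000, ebandUm = 300,
                           slideId = "fixture") {
  list(slide_id = slideId,
       tumor = cbind(c(0, widthUm, widthUm, 0), c(0, 0, depthUm, depthUm)),
       epidermis = cbind(c(0, widthUm, widthUm, 0), c(-ebandUm, -ebandUm, 0, 0)),
       pixel_size_um = 0.5)
}

rotatePoints <- function(pts, thetaDeg, center = c(0, 0)) {
  th <- thetaDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(as.matrix(pts), 2, center) %*% t(R), 2, center, "+")
}

rotateAnnotation <- function(ann, thetaDeg, center = c(0, 0)) {
  ann$tumor <- rotatePoints(ann$tumor, thetaDeg, center)
  ann$epidermis <- rotatePoints(ann$epidermis, thetaDeg, center)
  ann
}

# Shared small simulated cohort for survival tests.
signalCohort <- function(n, beta, seed, censoring = 0.3) {
  sim <- simulateCohort(cohortSimConfig(
    n_patients = n, beta = c(marker = beta), censoring_rate = censoring,
    seed = seed))
  data.frame(marker = sim$features$marker, time = sim$survival$time,
             event = sim$survival$event)
}
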