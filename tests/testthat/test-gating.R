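test_that("Otsu on a symmetric two-spike histogram splits at the midpoint", {
  sp <- otsuThreshold(c(rep(0, 500), rep(10, 500)), nBins = 256L)
  binWidth <- 10 / 256
  expect_lt(abs(sp@threshold - 5), binWidth + 1e-12)
  expect_equal(sp@omega0, 0.5)
  expect_equal(sp@omega1, 0.5)
  expect_gt(sp@threshold, min(0))
  expect_lt(sp@threshold, 10)
})

test_that("Otsu equals the naive exhaustive scan on seeded mixture fixtures", {
  for (seed in 1:8) {
    set.seed(seed)
    v <- c(rnorm(600, 10, 2), rnorm(400, 25, 3))
    expect_identical(otsuThreshold(v)@threshold, otsuOracle(v),
                     info = paste("seed", seed))
  }
})

test_that("percentile binning makes the Otsu split robust to a lone outlier", {
  set.seed(42)
  v <- c(rnorm(600, 10, 2), rnorm(400, 25, 3))
  t1 <- otsuThreshold(v)@threshold
  t2 <- otsuThreshold(c(v, 10 * max(v)))@threshold
  binWidth <- diff(quantile(v, c(0.01, 0.99), names = FALSE)) / 256
  expect_lt(abs(t1 - t2), binWidth + 1e-12)
})

test_that("Otsu rejects degenerate input", {
  expect_error(otsuThreshold(rep(3, 50)), class = "melbands_degenerate_error")
  expect_error(otsuThreshold(c(1, 2), nBins = 1L), class = "melbands_config_error")
})

test_that("foreground split partitions and conserves the input", {
  v <- c(rep(0, 500), rep(10, 500))
  sp <- otsuThreshold(v)
  parts <- splitForeground(v, sp)
  expect_length(parts$foreground, 500)
  expect_true(all(parts$foreground == 10))
  set.seed(3)
  v2 <- rlnorm(1000, 3, 1)
  parts2 <- splitForeground(v2, otsuThreshold(v2))
  expect_equal(length(parts2$background) + length(parts2$foreground), 1000L)
  expect_gt(length(parts2$foreground), 0L)
})

test_that("log-mixture EM recovers generating parameters from clean draws", {
  set.seed(7)
  n <- 2000
  z <- runif(n) < 0.6
  x <- ifelse(z, rnorm(n, 3, 0.3), rnorm(n, 1, 0.3))
  mix <- fitLogMixture(exp(x))
  expect_true(mix@converged)
  expect_lt(abs(mix@means[1] - 1), 0.1)
  expect_lt(abs(mix@means[2] - 3), 0.1)
  expect_lt(abs(mix@weights[1] - 0.4), 0.05)
  expect_lt(abs(mix@weights[2] - 0.6), 0.05)
  expect_lt(abs(mix@sds[1] - 0.3), 0.05)
})

test_that("log-mixture fit agrees with an independent EM implementation", {
  withr::local_package("mclust")
  set.seed(11)
  x <- c(rnorm(800, 1, 0.4), rnorm(1200, 2.8, 0.5))
  mix <- fitLogMixture(exp(x))
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mu <- sort(mc$parameters$mean)
  expect_lt(abs(mix@means[1] - mu[1]), 0.05)
  expect_lt(abs(mix@means[2] - mu[2]), 0.05)
})

test_that("EM objective trace is monotonically non-decreasing", {
  for (seed in c(2, 5, 9)) {
    set.seed(seed)
    x <- c(rnorm(300, 0, 1), rnorm(200, 2, 0.5))
    mix <- fitLogMixture(exp(x))
    d <- diff(mix@objective)
    expect_true(all(d > -1e-8 * abs(mix@objective[-1])),
                info = paste("seed", seed))
  }
})

test_that("log-mixture rejects degenerate foregrounds", {
  expect_error(fitLogMixture(rep(5, 100)), class = "melbands_degenerate_error")
  expect_error(fitLogMixture(c(1, 2, 3)), class = "melbands_gating_error")
})

test_that("mixture intersection is exact at the symmetric midpoint", {
  mix <- new("LogMixture", weights = c(0.5, 0.5), means = c(0, 4),
             sds = c(1, 1), nIter = 1L, converged = TRUE, objective = 0)
  res <- mixtureIntersection(mix)
  expect_false(res$fallbackUsed)
  expect_lt(abs(res$logThreshold - 2), 1e-10)
})

test_that("unequal-sd intersections match a bisection oracle", {
  cases <- list(c(0.5, 0.5, 0, 4, 1, 2), c(0.3, 0.7, 1, 5, 0.8, 1.6),
                c(0.6, 0.4, -2, 3, 1.5, 0.7))
  for (cs in cases) {
    mix <- new("LogMixture", weights = cs[1:2], means = cs[3:4],
               sds = cs[5:6], nIter = 1L, converged = TRUE, objective = 0)
    res <- mixtureIntersection(mix)
    expect_false(res$fallbackUsed)
    gap <- function(x) cs[1] * dnorm(x, cs[3], cs[5]) - cs[2] * dnorm(x, cs[4], cs[6])
    oracle <- uniroot(gap, lower = cs[3], upper = cs[4], tol = 1e-12)$root
    expect_lt(abs(res$logThreshold - oracle), 1e-8)
    # residual at the returned root
    expect_lt(abs(gap(res$logThreshold)), 1e-8)
  }
})

test_that("extreme weight imbalance triggers the closest-density fallback", {
  mix <- new("LogMixture", weights = c(0.999, 0.001), means = c(0, 1),
             sds = c(1, 1), nIter = 1L, converged = TRUE, objective = 0)
  res <- mixtureIntersection(mix)
  expect_true(res$fallbackUsed)
  expect_gte(res$logThreshold, 0)
  expect_lte(res$logThreshold, 1)
})

test_that("full gate recovers latent labels at 6-sd separation", {
  mm <- defaultMarkerMix(6)
  mm$ki67$fg_fraction <- 0.5
  sim <- simulateSlide(slideSimConfig(marker_mix = mm, seed = 21))
  g <- gateMarker(sim$cells, "ki67")
  expect_false(g$gate@failed)
  expect_gte(mean(g$positive == sim$truth$true_ki67), 0.99)
})

test_that("gating is invariant to a global multiplicative intensity rescale", {
  sim <- simulateSlide(slideSimConfig(seed = 5))
  g1 <- gateMarker(sim$cells, "ki67")
  cells2 <- sim$cells
  cells2$ki67_nucleus_mean <- cells2$ki67_nucleus_mean * 37.5
  g2 <- gateMarker(cells2, "ki67")
  expect_identical(g1$positive, g2$positive)
  expect_lt(abs(g2$gate@logThreshold - g1$gate@logThreshold - log(37.5)), 1e-6)
})

test_that("positive fraction is non-increasing in the final threshold", {
  sim <- simulateSlide(slideSimConfig(seed = 6))
  g <- gateMarker(sim$cells, "ki67")
  v <- sim$cells$ki67_nucleus_mean
  fr <- vapply(g$gate@logThreshold + c(-0.5, -0.1, 0, 0.1, 0.5),
               function(t) mean(log(v) > g$gate@otsu@threshold & log(v) >= t),
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("empty or malformed cell tables yield failed gates or errors", {
  empty <- data.frame(ki67_nucleus_mean = numeric(0))
  g <- gateMarker(empty, "ki67")
  expect_true(g$gate@failed)
  expect_length(g$positive, 0L)
  expect_error(gateMarker(data.frame(x = 1:5), "ki67"),
               class = "melbands_format_error")
  # constant intensities: gate fails, every cell negative
  const <- data.frame(ki67_nucleus_mean = rep(4, 50))
  gc <- gateMarker(const, "ki67")
  expect_true(gc$gate@failed)
  expect_false(any(gc$positive))
})
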