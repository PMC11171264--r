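test_that("slide simulation honours density, containment and determinism", {
  cfg <- slideSimConfig(tumor_depth_mm = 3, tumor_width_mm = 6,
                        cell_density_per_mm2 = 200, seed = 1)
  sim <- simulateSlide(cfg)
  lam <- 200 * 18
  expect_gt(nrow(sim$cells), qpois(1e-6, lam))
  expect_lt(nrow(sim$cells), qpois(1 - 1e-6, lam))
  inside <- melbands:::pointsInPolygon(
    cbind(sim$cells$centroid_x_um, sim$cells$centroid_y_um),
    sim$annotation$tumor)
  expect_true(all(inside))
  # epidermis strip is adjacent to the superficial tumor edge
  expect_equal(max(sim$annotation$epidermis[, 2]), min(sim$annotation$tumor[, 2]))
  # identical seeds give byte-identical outputs
  expect_identical(sim, simulateSlide(cfg))
  expect_false(identical(sim$cells, simulateSlide(slideSimConfig(seed = 2))$cells))
})

test_that("blob-shaped slides keep cells inside and band correctly", {
  cfg <- slideSimConfig(tumor_shape = "blob", tumor_depth_mm = 2,
                        tumor_width_mm = 3, cell_density_per_mm2 = 100, seed = 4)
  sim <- simulateSlide(cfg)
  inside <- melbands:::pointsInPolygon(
    cbind(sim$cells$centroid_x_um, sim$cells$centroid_y_um),
    sim$annotation$tumor)
  expect_true(all(inside))
  expect_true(all(sim$truth$true_band %in% c("superficial", "middle", "invasive")))
})

test_that("zero band shift leaves per-band nucleus sizes indistinguishable", {
  sim <- simulateSlide(slideSimConfig(seed = 17))
  pv <- anova(lm(sim$cells$nucleus_area_um2 ~ sim$truth$true_band))$`Pr(>F)`[1]
  expect_gt(pv, 0.01)
  # and a planted invasive shift is recovered in the truth-banded means
  shift <- c(superficial = 0, middle = 0, invasive = 8)
  sim2 <- simulateSlide(slideSimConfig(
    nucleus_area_band_shift_um2 = shift, seed = 17))
  m <- tapply(sim2$cells$nucleus_area_um2, sim2$truth$true_band, mean)
  expect_gt(m[["invasive"]] - m[["superficial"]], 8 - 2)
})

test_that("marker intensities are bimodal on the log scale when separated", {
  sim <- simulateSlide(slideSimConfig(cell_density_per_mm2 = 400, seed = 9))
  lv <- log(sim$cells$ki67_nucleus_mean)
  km <- kmeans(lv, centers = quantile(lv, c(0.2, 0.95)))
  sep <- abs(diff(km$centers)) /
    sqrt(max(tapply(lv, km$cluster, var)))
  expect_gt(sep, 2)  # two-means separation check
})

test_that("slide configuration invariants are enforced", {
  expect_error(slideSimConfig(tumor_depth_mm = -1), class = "melbands_config_error")
  mm <- defaultMarkerMix()
  mm$ki67$fg_fraction <- 1
  expect_error(slideSimConfig(marker_mix = mm), class = "melbands_config_error")
  mm2 <- defaultMarkerMix()
  mm2$s100$fg_log_mean <- mm2$s100$bg_log_mean - 1
  expect_error(slideSimConfig(marker_mix = mm2), class = "melbands_config_error")
})

test_that("cohort simulation: null signal, forced events and determinism", {
  cfg <- cohortSimConfig(n_patients = 200, beta = c(f = 0),
                         censoring_rate = 0.3, seed = 7)
  sim <- simulateCohort(cfg)
  cc <- harrellC(sim$truth$lp + rnorm(200, 0, 1e-9), sim$survival$time,
                 sim$survival$event)
  expect_lt(abs(cc - 0.5), 0.05)
  expect_identical(sim, simulateCohort(cfg))
  full <- simulateCohort(cohortSimConfig(n_patients = 50, beta = c(f = 0.5),
                                         censoring_rate = 0, seed = 3))
  expect_true(all(full$survival$event))
})

test_that("event fraction decreases with the censoring rate and hits its target", {
  rates <- c(0, 0.2, 0.5, 0.8)
  evFrac <- sapply(rates, function(r) {
    mean(sapply(1:5, function(s)
      mean(simulateCohort(cohortSimConfig(
        n_patients = 150, beta = c(f = 0.3), censoring_rate = r,
        seed = 100 + s))$survival$event)))
  })
  expect_true(all(diff(evFrac) < 0))
  expect_lt(abs(evFrac[3] - 0.5), 0.1)  # calibration: ~50% censored
})

test_that("a strong planted effect is recovered by the Cox stage", {
  d <- signalCohort(n = 400, beta = 0.7, seed = 23)
  fit <- coxFit(d, "marker")
  tab <- resultTable(fit)
  expect_lt(tab$lower, exp(0.7))  # Wald CI brackets the true hazard ratio
  expect_gt(tab$upper, exp(0.7))
  expect_lt(abs(tab$beta - 0.7), 3 * tab$se)
})

test_that("cohort configuration invariants are enforced", {
  expect_error(cohortSimConfig(n_patients = 1, beta = c(f = 0)),
               class = "melbands_config_error")
  expect_error(cohortSimConfig(n_patients = 10, beta = c(f = 0),
                               censoring_rate = 1),
               class = "melbands_config_error")
  expect_error(cohortSimConfig(n_patients = 10, beta = c(f = 0),
                               baseline_hazard_scale = -2),
               class = "melbands_config_error")
  expect_error(cohortSimConfig(n_patients = 10, beta = 0.5),
               class = "melbands_config_error")
})
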