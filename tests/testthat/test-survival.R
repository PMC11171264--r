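test_that("Cox fit matches the Breslow partial-likelihood grid oracle", {
  toy <- data.frame(time = 1:6, event = rep(TRUE, 6),
                    x = c(1, 0, 1, 0, 1, 0))
  fit <- coxFit(toy, "x")
  oracle <- coxGridOracle(toy$time, toy$event, toy$x)
  expect_lt(abs(resultTable(fit)$beta - oracle), 1e-4)
  # tied event times exercise the Breslow approximation
  tied <- data.frame(time = c(2, 2, 3, 3, 5, 5, 7, 9),
                     event = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
                     x = c(0.5, 1.2, -0.3, 0.8, 1.5, -1, 0.2, -0.7))
  fit2 <- coxFit(tied, "x")
  oracle2 <- coxGridOracle(tied$time, tied$event, tied$x)
  expect_lt(abs(resultTable(fit2)$beta - oracle2), 1e-4)
  # the reported log partial likelihood is the one the oracle maximizes
  expect_equal(fit2@logLik,
               breslowLogPL(resultTable(fit2)$beta, tied$time, tied$event, tied$x),
               tolerance = 1e-6)
})

test_that("Cox results are invariant to covariate location shifts", {
  d <- signalCohort(n = 120, beta = 0.5, seed = 5)
  f1 <- coxFit(d, "marker")
  d2 <- d; d2$marker <- d2$marker + 100
  f2 <- coxFit(d2, "marker")
  expect_equal(resultTable(f1)$beta, resultTable(f2)$beta, tolerance = 1e-8)
  expect_equal(resultTable(f1)$se, resultTable(f2)$se, tolerance = 1e-8)
  expect_equal(concordanceIndex(f1), concordanceIndex(f2))
})

test_that("degenerate designs are rejected", {
  d <- signalCohort(n = 50, beta = 0.5, seed = 6)
  d$const <- 1
  expect_error(coxFit(d, "const"), class = "melbands_validation_error")
  d$dup <- 2 * d$marker + 3
  expect_error(coxFit(d, c("marker", "dup")), class = "melbands_validation_error")
  expect_error(coxFit(d[d$event == FALSE, ][1:3, ], "marker"),
               class = "melbands_validation_error")
})

test_that("Harrell's C handles perfect, antiperfect and tied rankings", {
  expect_equal(harrellC(c(3, 2, 1), 1:3, rep(TRUE, 3)), 1)
  expect_equal(harrellC(c(1, 2, 3), 1:3, rep(TRUE, 3)), 0)
  expect_equal(harrellC(c(2, 2, 2), 1:3, rep(TRUE, 3)), 0.5)
  expect_error(harrellC(1:3, 1:3, rep(FALSE, 3)),
               class = "melbands_validation_error")
})

test_that("Harrell's C equals exhaustive pair enumeration with ties and censoring", {
  set.seed(19)
  for (rep in 1:3) {
    time <- sample(1:20, 50, replace = TRUE)       # many tied times
    event <- runif(50) < 0.7
    risk <- round(rnorm(50), 1)                    # some tied scores
    expect_equal(harrellC(risk, time, event), bruteForceC(risk, time, event))
  }
  # on tie-free times the established implementation agrees exactly
  time <- rexp(60); event <- runif(60) < 0.6; risk <- rnorm(60)
  cc <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)$concordance
  expect_equal(harrellC(risk, time, event), as.numeric(cc))
})

test_that("bootstrap concordance CI is deterministic and detects signal", {
  d <- signalCohort(n = 200, beta = 1, seed = 11)
  b1 <- bootstrapConcordance(d, "marker", B = 200, seed = 42)
  b2 <- bootstrapConcordance(d, "marker", B = 200, seed = 42)
  expect_identical(b1$ci, b2$ci)
  expect_gt(b1$ci[1], 0.5)   # strong signal: CI excludes chance
  expect_lt(b1$ci[1], b1$concordance)
  expect_gt(b1$ci[2], b1$concordance)
})

test_that("null-cohort concordance CI typically covers 0.5", {
  hits <- sum(sapply(1:10, function(s) {
    d <- signalCohort(n = 80, beta = 0, seed = 300 + s)
    ci <- bootstrapConcordance(d, "marker", B = 150, seed = s)$ci
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }))
  expect_gte(hits, 8)
})

test_that("LOOCV concordance works from minimal n to strong-signal consistency", {
  tiny <- data.frame(time = c(1, 2, 3), event = c(TRUE, TRUE, TRUE),
                     x = c(3, 1, 2))
  lo <- loocvConcordance(tiny, "x", B = 100, seed = 1)
  expect_gte(lo$concordance, 0)
  expect_lte(lo$concordance, 1)
  d <- signalCohort(n = 300, beta = 1, seed = 13)
  app <- concordanceIndex(coxFit(d, "marker"))
  lo2 <- loocvConcordance(d, "marker", B = 100, seed = 2)
  expect_lt(abs(lo2$concordance - app), 0.05)
  expect_equal(lo2$nSkipped, 0L)
})

test_that("the univariable screen recovers a planted factor and ignores order", {
  set.seed(29)
  sim <- simulateCohort(cohortSimConfig(
    n_patients = 200, beta = c(nuclei_size_invasive = 0.5, age = 0),
    censoring_rate = 0.2, seed = 29))
  d <- cbind(sim$features, sim$survival[c("time", "event")])
  sc <- univariateScreen(d, c("nuclei_size_invasive", "age"), B = 150, seed = 3)
  row <- sc[sc$factor == "nuclei_size_invasive", ]
  expect_gt(row$hr, 1)
  expect_lt(row$p, 0.05)
  expect_gt(row$concordance, 0.5)
  sc2 <- univariateScreen(d, c("age", "nuclei_size_invasive"), B = 150, seed = 3)
  expect_equal(sc2[order(sc2$factor), names(sc2) != "label"],
               sc[order(sc$factor), names(sc) != "label"],
               ignore_attr = TRUE)
})

test_that("the screen excludes mostly-missing factors with a warning", {
  d <- signalCohort(n = 60, beta = 0.5, seed = 17)
  d$sparse <- NA_real_
  d$sparse[1:10] <- rnorm(10)
  expect_warning(sc <- univariateScreen(d, c("marker", "sparse"), B = 100, seed = 1),
                 "sparse")
  expect_false("sparse" %in% sc$factor)
})

test_that("multivariable models follow the base-plus-one-size-factor schema", {
  set.seed(37)
  sim <- simulateCohort(cohortSimConfig(
    n_patients = 120,
    beta = c(mitosis = 0.3, thickness = 0.4, nuclei_size_invasive = 0.3,
             tumor_nuclei_size_invasive = 0, coloc_nuclei_size_invasive = 0),
    censoring_rate = 0.2, seed = 37))
  d <- cbind(sim$features, sim$survival[c("time", "event")])
  models <- multivariableModels(d, B = 120, seed = 5)
  expect_named(models, c("base", "nuclei_size_invasive",
                         "tumor_nuclei_size_invasive",
                         "coloc_nuclei_size_invasive"))
  expect_equal(nrow(resultTable(models$base)), 2L)
  expect_equal(nrow(resultTable(models$nuclei_size_invasive)), 3L)
  for (m in models) {
    expect_false(anyNA(m@concordanceCI))
    expect_false(is.na(m@loocvC))
    expect_true(m@concordance >= 0 && m@concordance <= 1)
  }
  tab <- coxModelTable(models)
  expect_true(all(c("model", "term", "hr", "lower", "upper", "p",
                    "c_index", "loocv_c") %in% names(tab)))
  expect_equal(nrow(tab), 2L + 3L * 3L)
  # a factor duplicating thickness is rejected as collinear
  d$dup_thickness <- d$thickness
  expect_error(multivariableModels(d, sizeFactors = "dup_thickness", B = 120),
               class = "melbands_validation_error")
})

test_that("cohort summary arithmetic matches hand computation", {
  cl <- tableTwoLikeClinical()
  sm <- summarizeCohort(cl)
  expect_equal(sm$n, 26L)
  expect_equal(sm$median_age, 62.5)
  expect_equal(sm$age_range, c(24, 78))
  expect_equal(sm$endpoints$OS$n_event, 16L)
  expect_equal(sm$endpoints$OS$event_pct, 61.5)
  expect_equal(sm$endpoints$PFS$event_pct, 69.2)
  expect_equal(sm$endpoints$OS$median_time, 35.5)
  expect_equal(sm$sex$pct[sm$sex$sex == "male"], 76.9)
  single <- cl$os[1, ]
  s1 <- summarizeCohort(single)
  expect_equal(s1$median_age, single$age)
  expect_equal(s1$age_range, rep(single$age, 2))
})
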