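# Shared fixture: a rectangle slide with truth-derived marker flags so the
# feature machinery is tested independently of gating accuracy.
featureFixture <- function(seed = 31, shift = c(superficial = 0, middle = 0,
                                                invasive = 0)) {
  sim <- simulateSlide(slideSimConfig(nucleus_area_band_shift_um2 = shift,
                                      seed = seed))
  geom <- partitionBands(sim$annotation, resolution = 10)
  cells <- sim$cells
  cells$ki67_pos <- sim$truth$true_ki67
  cells$s100_pos <- sim$truth$true_s100
  cells <- annotateCells(cells, geom)
  cells <- classifyCategories(cells)
  list(sim = sim, geom = geom, cells = cells)
}

test_that("category flags follow the dual-positivity definitions", {
  df <- data.frame(ki67_pos = c(TRUE, TRUE, FALSE, FALSE),
                   s100_pos = c(TRUE, FALSE, TRUE, FALSE))
  out <- classifyCategories(df)
  expect_equal(out$cat_total, rep(TRUE, 4))
  expect_equal(out$cat_tumor, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$cat_coloc, c(TRUE, FALSE, FALSE, FALSE))
  # colocalized is exactly the intersection on any input
  fx <- featureFixture()
  expect_identical(fx$cells$cat_coloc, fx$cells$cat_tumor & fx$cells$ki67_pos)
  expect_error(classifyCategories(data.frame(x = 1)),
               class = "melbands_validation_error")
})

test_that("band aggregates: densities are count/area and counts conserve", {
  fx <- featureFixture()
  agg <- bandAggregates(fx$cells, fx$geom)
  expect_equal(agg$density_total, agg$n_total / agg$area_mm2)
  ov <- agg[agg$band == "overall", ]
  per <- agg[agg$band != "overall", ]
  for (cat in c("total", "tumor", "coloc"))
    expect_equal(sum(per[[paste0("n_", cat)]]), ov[[paste0("n_", cat)]])
  expect_equal(ov$area_mm2, sum(per$area_mm2))
})

test_that("empty categories yield missing mean sizes, not zeros", {
  fx <- featureFixture()
  cells <- fx$cells
  cells$cat_coloc <- FALSE
  ws <- capture_warnings(agg <- bandAggregates(cells, fx$geom))
  expect_length(ws, 4L)  # one per band plus overall
  expect_true(all(grepl("coloc", ws)))
  expect_true(all(is.na(agg$mean_size_coloc)))
  expect_true(all(agg$n_coloc == 0))
})

test_that("assembled features satisfy the ratio and unit identities", {
  fx <- featureFixture()
  clin <- data.frame(patient_id = "P1", age = 60, mitosis = 4, thickness = 3.2)
  agg <- bandAggregates(fx$cells, fx$geom)
  feat <- assembleFeatures(clin, agg, fx$geom)
  expect_equal(feat$estimated_thickness, fx$geom@thicknessUm / 1000)
  rcols <- grep("ratio", names(feat), value = TRUE)
  rv <- unlist(feat[rcols])
  expect_true(all(rv >= 0 & rv <= 1, na.rm = TRUE))
  for (b in c("invasive", "middle", "superficial", "overall")) {
    a <- agg[agg$band == b, ]
    if (a$n_tumor < a$n_total && a$n_tumor > 0)
      expect_gte(feat[[paste0("coloc_tumor_ratio_", b)]],
                 feat[[paste0("coloc_total_ratio_", b)]])
  }
  # density arithmetic spot check
  inv <- agg[agg$band == "invasive", ]
  expect_equal(feat$cell_density_invasive, inv$n_total / inv$area_mm2)
})

test_that("a planted invasive-band nucleus-size shift is recovered", {
  s <- 6
  fx <- featureFixture(seed = 41, shift = c(superficial = 0, middle = 0,
                                            invasive = s))
  agg <- bandAggregates(fx$cells, fx$geom)
  mInv <- agg$mean_size_total[agg$band == "invasive"]
  mSup <- agg$mean_size_total[agg$band == "superficial"]
  nInv <- agg$n_total[agg$band == "invasive"]
  nSup <- agg$n_total[agg$band == "superficial"]
  se <- 8 * sqrt(1 / nInv + 1 / nSup)  # generator sd is 8 um^2
  expect_lt(abs((mInv - mSup) - s), 2 * se + 0.5)
})

test_that("every factor in the dictionary has a label and vice versa", {
  fx <- featureFixture()
  clin <- data.frame(patient_id = "P1", age = 60, mitosis = 4, thickness = 3.2)
  feat <- assembleFeatures(clin, bandAggregates(fx$cells, fx$geom), fx$geom)
  dict <- factorDictionary()
  factorCols <- setdiff(names(feat), "patient_id")
  expect_true(all(factorCols %in% names(dict)))
})
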