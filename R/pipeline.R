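# End-to-end pipeline driver: gate -> bands -> features -> survival ->
# correlations, over either simulated slides or on-disk inputs, writing a
# manifest and all tables so every figure-level number also exists as CSV.

#' Configuration for the bundled demonstration pipeline
#'
#' Describes a simulated cohort exercising the full pipeline: each patient
#' gets one simulated slide whose mean nucleus area is driven by a latent
#' patient-level severity score, and a survival outcome whose log-hazard is
#' proportional to the same score — so invasive-band nucleus size is a
#' genuinely prognostic factor that the pipeline should recover. Slides are
#' 2 mm deep by 4 mm wide at 150 cells/mm² to keep a full run desk-scale.
#'
#' @param nPatients number of patients (default 40).
#' @param effectBeta log-hazard per standard deviation of the latent severity
#'   score (default 0.8).
#' @param sizePerSd shift of mean nucleus area (µm²) per severity sd
#'   (default 4).
#' @param thicknessPerSd shift of clinical Breslow thickness (mm) per severity
#'   sd (default 0.3): thicker tumors carry larger nuclei, mirroring the
#'   correlation structure the method is meant to expose.
#' @param tumorDepthMm,tumorWidthMm,cellDensity slide geometry and density.
#' @param resolution band raster resolution, µm (default 10).
#' @param bootstrapB bootstrap replicates for concordance CIs (default 500).
#' @param censoringRate expected censored fraction (default 0.25).
#' @param seed master seed; every stage's randomness derives from it.
#' @return list of class `PipelineConfig`.
#' @export
demoPipelineConfig <- function(nPatients = 40L, effectBeta = 0.8,
                               sizePerSd = 4, thicknessPerSd = 0.3,
                               tumorDepthMm = 2,
                               tumorWidthMm = 4, cellDensity = 150,
                               resolution = 10, bootstrapB = 500L,
                               censoringRate = 0.25, seed = 1L) {
  if (nPatients < 5L) mbConfigError("the demo pipeline needs >= 5 patients")
  structure(list(nPatients = as.integer(nPatients), effectBeta = effectBeta,
                 sizePerSd = sizePerSd, thicknessPerSd = thicknessPerSd,
                 tumorDepthMm = tumorDepthMm,
                 tumorWidthMm = tumorWidthMm, cellDensity = cellDensity,
                 resolution = resolution, bootstrapB = as.integer(bootstrapB),
                 censoringRate = censoringRate, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes, per patient: slide simulation, two-phase gating of Ki67 and
#' S100, band geometry, cell annotation, category classification, band
#' aggregation and feature assembly; then the univariable Cox screen, the
#' multivariable models (base + one invasive-band nuclei-size factor each),
#' the factor correlation matrices, and the cohort summary. Per-patient
#' failures are logged and the patient excluded; a stage failure halts with a
#' stage-tagged error. Identical seeds yield identical outputs.
#'
#' @param config a [demoPipelineConfig()].
#' @param outDir optional output directory; when given, features, result
#'   tables, correlations, gates and a manifest are written there.
#' @param figures also write diagnostic figures (PNG) to `outDir`
#'   (default FALSE).
#' @return list with `features` (data.frame incl. time/event), `clinical`,
#'   `summary`, `univariate` (screen table), `multivariable` (list of
#'   [CoxModelResult-class]), `multivariableTable`, `correlations` (list of
#'   `melbandsCorrelation` by category), `gates`, `exclusions`.
#' @export
runPipeline <- function(config, outDir = NULL, figures = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  n <- config$nPatients
  sev <- withSeed(config$seed, stats::rnorm(n))
  slideSeeds <- withSeed(config$seed + 1L, sample.int(2^30, n))
  clinicalSim <- withSeed(config$seed + 2L, {
    data.frame(patient_id = sprintf("P%03d", seq_len(n)),
               age = round(stats::rnorm(n, 60, 10)),
               mitosis = stats::rpois(n, 4),
               thickness = round(pmax(1.3, config$tumorDepthMm +
                                        (config$thicknessPerSd %||% 0) * sev +
                                        stats::rnorm(n, 0, 0.4)), 2),
               stringsAsFactors = FALSE)
  })
  survTruth <- withSeed(config$seed + 4L,
    weibullPHSurvival(config$effectBeta * sev, scale = 36, shape = 1.2,
                      censoringRate = config$censoringRate))

  features <- vector("list", n)
  gates <- list()
  exclusions <- data.frame(patient_id = character(0), reason = character(0))
  cellsPooled <- list()
  for (i in seq_len(n)) {
    pid <- clinicalSim$patient_id[i]
    res <- tryCatch({
      cfg <- slideSimConfig(
        tumor_depth_mm = config$tumorDepthMm,
        tumor_width_mm = config$tumorWidthMm,
        cell_density_per_mm2 = config$cellDensity,
        nucleus_area_base_um2 = 40 + config$sizePerSd * sev[i],
        seed = slideSeeds[i])
      sim <- simulateSlide(cfg, slideId = pid)
      gk <- gateMarker(sim$cells, "ki67")
      gs <- gateMarker(sim$cells, "s100")
      if (gk$gate@failed || gs$gate@failed)
        mbGatingError("gate failed: %s", paste(gk$gate@failureReason,
                                               gs$gate@failureReason))
      cells <- sim$cells
      cells$ki67_pos <- gk$positive
      cells$s100_pos <- gs$positive
      geom <- partitionBands(sim$annotation, resolution = config$resolution)
      cells <- annotateCells(cells, geom)
      cells <- classifyCategories(cells)
      agg <- suppressWarnings(bandAggregates(cells, geom))
      feat <- assembleFeatures(clinicalSim[i, ], agg, geom)
      list(feat = feat, gates = list(ki67 = gk$gate, s100 = gs$gate),
           cells = cells)
    }, melbands_error = function(e) e)
    if (inherits(res, "condition")) {
      exclusions <- rbind(exclusions,
                          data.frame(patient_id = pid,
                                     reason = conditionMessage(res)))
      next
    }
    features[[i]] <- res$feat
    gates[[pid]] <- res$gates
    cellsPooled[[pid]] <- res$cells
  }
  features <- do.call(rbind, features)
  if (is.null(features) || nrow(features) < 5L)
    mbStop("melbands_pipeline_error",
           "pipeline stage 'features': fewer than 5 patients survived QC")
  features$time <- survTruth$time[match(features$patient_id, clinicalSim$patient_id)]
  features$event <- survTruth$event[match(features$patient_id, clinicalSim$patient_id)]

  factorCols <- setdiff(names(features), c("patient_id", "time", "event"))
  screen <- suppressWarnings(
    univariateScreen(features, factorCols, B = config$bootstrapB,
                     seed = config$seed + 10L))
  models <- multivariableModels(features, B = config$bootstrapB,
                                seed = config$seed + 20L)
  modelTable <- coxModelTable(models)

  corFactors <- list(
    nuclei_size = c("mitosis", "thickness", paste0("nuclei_size_", c(
      "invasive", "middle", "superficial", "overall"))),
    tumor_nuclei_size = c("mitosis", "thickness", paste0("tumor_nuclei_size_", c(
      "invasive", "middle", "superficial", "overall"))),
    coloc_nuclei_size = c("mitosis", "thickness", paste0("coloc_nuclei_size_", c(
      "invasive", "middle", "superficial", "overall"))))
  correlations <- lapply(corFactors, function(fs)
    suppressWarnings(correlationMatrix(features, fs)))

  clinical <- cbind(clinicalSim[match(features$patient_id, clinicalSim$patient_id), ],
                    time = features$time, event = features$event,
                    endpoint = "simulated")
  summary <- summarizeCohort(clinical)

  out <- list(features = features, clinical = clinical, summary = summary,
              univariate = screen, multivariable = models,
              multivariableTable = modelTable, correlations = correlations,
              gates = gates, cells = cellsPooled, exclusions = exclusions,
              config = config)
  if (!is.null(outDir)) writePipelineBundle(out, outDir, figures = figures)
  out
}

writePipelineBundle <- function(result, outDir, figures = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$features, file.path(outDir, "features.csv"),
                   row.names = FALSE)
  writeClinical(result$clinical, file.path(outDir, "clinical.csv"))
  utils::write.csv(result$univariate, file.path(outDir, "univariate.csv"),
                   row.names = FALSE)
  utils::write.csv(result$multivariableTable,
                   file.path(outDir, "multivariable.csv"), row.names = FALSE)
  for (nm in names(result$correlations))
    writeCorrelation(result$correlations[[nm]],
                     file.path(outDir, sprintf("correlation_%s.csv", nm)))
  if (nrow(result$exclusions))
    utils::write.csv(result$exclusions, file.path(outDir, "exclusions.csv"),
                     row.names = FALSE)
  gateDir <- file.path(outDir, "gates")
  dir.create(gateDir, showWarnings = FALSE)
  for (pid in names(result$gates))
    for (mk in names(result$gates[[pid]]))
      writeGate(result$gates[[pid]][[mk]],
                file.path(gateDir, sprintf("%s_%s.json", pid, mk)))
  for (nm in names(result$multivariable))
    writeCoxResult(result$multivariable[[nm]],
                   file.path(outDir, sprintf("cox_%s.json", nm)))
  manifest <- list(
    config = unclass(result$config),
    n_patients_included = nrow(result$features),
    n_excluded = nrow(result$exclusions),
    provenance = provenanceBlock(seed = result$config$seed,
                                 config = unclass(result$config)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (figures) {
    pid1 <- names(result$cells)[1]
    gg <- list(
      boxplots = plotNucleiBoxplots(do.call(rbind, result$cells)),
      forest = plotConcordanceForest(result$univariate))
    for (nm in names(result$correlations))
      gg[[paste0("heatmap_", nm)]] <- plotCorrelationHeatmap(result$correlations[[nm]])
    for (nm in names(gg)) {
      grDevices::png(file.path(outDir, paste0(nm, ".png")),
                     width = 1400, height = 1000, res = 150)
      print(gg[[nm]])
      grDevices::dev.off()
    }
  }
  invisible(outDir)
}
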