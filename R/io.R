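# Readers/writers for the on-disk artifacts: detection-dialect cell tables
# (CSV), tumor/epidermis annotations (GeoJSON), clinical tables (CSV), gates
# and model fits (JSON), feature tables (CSV). Readers validate and reject
# rather than silently coerce; writers round-trip at documented precision
# (coordinates to 0.01 um, intensities and areas to 6 significant digits).

markerNames <- c("dapi", "ki67", "s100")
compartmentNames <- c("nucleus", "cytoplasm", "membrane")

#' Required cell-table columns (canonical names)
#' @return character vector of canonical column names.
#' @export
cellTableColumns <- function() {
  c("cell_id", "centroid_x_um", "centroid_y_um", "nucleus_area_um2",
    as.vector(outer(markerNames, compartmentNames,
                    function(m, cp) paste(m, cp, "mean", sep = "_"))))
}

#' Column map for the common detection-software export dialect
#'
#' Maps canonical column names to the headers produced by the usual
#' digital-pathology detection export ("Centroid X µm", per-channel
#' "Ki67: Nucleus: Mean", ...). Pass to [readCellTable()] when reading such
#' exports; any named character vector `canonical = file_header` works.
#'
#' @return named character vector.
#' @export
detectionDialectMap <- function() {
  base <- c(cell_id = "Object ID",
            centroid_x_um = "Centroid X µm",
            centroid_y_um = "Centroid Y µm",
            nucleus_area_um2 = "Nucleus: Area µm^2")
  lab <- c(dapi = "DAPI", ki67 = "Ki67", s100 = "S100")
  cp <- c(nucleus = "Nucleus", cytoplasm = "Cytoplasm", membrane = "Membrane")
  for (m in markerNames) for (k in compartmentNames) {
    base[paste(m, k, "mean", sep = "_")] <-
      sprintf("%s: %s: Mean", lab[[m]], cp[[k]])
  }
  base
}

#' Read a per-cell detection table
#'
#' @param path CSV path.
#' @param columnMap optional named character vector mapping canonical column
#'   names (see [cellTableColumns()]) to the file's headers.
#' @return data.frame of validated cell records; rows failing validation
#'   (non-positive nucleus area, negative or non-finite intensity or
#'   coordinate) are dropped and reported in the `errorReport` attribute
#'   (data.frame with `row` and `reason`).
#' @export
readCellTable <- function(path, columnMap = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(columnMap)) {
    for (canon in names(columnMap)) {
      j <- match(columnMap[[canon]], names(df))
      if (!is.na(j)) names(df)[j] <- canon
    }
  }
  need <- cellTableColumns()
  missing <- setdiff(need, names(df))
  if (length(missing))
    mbFormatError("cell table '%s' is missing required column(s): %s",
                  basename(path), paste(missing, collapse = ", "))
  numCols <- setdiff(need, "cell_id")
  bad <- data.frame(row = integer(0), reason = character(0))
  reasons <- rep(NA_character_, nrow(df))
  for (cl in numCols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    df[[cl]] <- v
    nf <- !is.finite(v)
    reasons[nf & is.na(reasons)] <- sprintf("non-numeric %s", cl)
  }
  badArea <- df$nucleus_area_um2 <= 0 & is.na(reasons)
  reasons[badArea] <- "non-positive nucleus_area_um2"
  intCols <- grep("_mean$", need, value = TRUE)
  negInt <- rowSums(as.matrix(df[intCols]) < 0) > 0
  reasons[negInt & is.na(reasons)] <- "negative intensity"
  drop <- !is.na(reasons)
  if (any(drop))
    bad <- data.frame(row = which(drop), reason = reasons[drop])
  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "errorReport") <- bad
  out
}

#' @rdname readCellTable
#' @param cells cell data.frame to write.
#' @export
writeCellTable <- function(cells, path) {
  out <- cells
  for (cl in c("centroid_x_um", "centroid_y_um"))
    if (cl %in% names(out)) out[[cl]] <- round(out[[cl]], 2)
  for (cl in grep("_mean$|_um2$", names(out), value = TRUE))
    out[[cl]] <- signif(out[[cl]], 6)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

ringIsSimple <- function(poly) {
  p <- openRing(as.matrix(poly))
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  seg <- function(i) rbind(p[i, ], p[if (i == n) 1L else i + 1L, ])
  inter <- function(a, b) {
    d1 <- a[2, ] - a[1, ]; d2 <- b[2, ] - b[1, ]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((b[1, 1] - a[1, 1]) * d2[2] - (b[1, 2] - a[1, 2]) * d2[1]) / den
    u <- ((b[1, 1] - a[1, 1]) * d1[2] - (b[1, 2] - a[1, 2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) next
      if (inter(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

geojsonPolygonFeature <- function(poly, classification) {
  ring <- closeRing(as.matrix(round(poly, 2)))
  list(type = "Feature",
       properties = list(classification = list(name = classification)),
       geometry = list(type = "Polygon",
                       coordinates = list(lapply(seq_len(nrow(ring)),
                                                 function(i) as.numeric(ring[i, ])))))
}

#' Read a slide annotation (GeoJSON)
#'
#' Expects a FeatureCollection with exactly one polygon classified "tumor"
#' and one classified "epidermis" (QuPath-style `classification` property,
#' either a string or an object with a `name`). Coordinates are in µm.
#'
#' @param path GeoJSON path.
#' @param slideId slide identifier (default: file name without extension).
#' @return list with `slide_id`, `tumor` and `epidermis` polygon matrices and
#'   `pixel_size_um` (NA unless stored in the file's top-level properties).
#' @export
readAnnotation <- function(path, slideId = NULL) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$type) || js$type != "FeatureCollection")
    mbFormatError("annotation '%s' is not a GeoJSON FeatureCollection", basename(path))
  getClass <- function(f) {
    cl <- f$properties$classification
    if (is.list(cl)) cl$name else cl
  }
  polys <- list()
  for (f in js$features) {
    cls <- tolower(getClass(f) %||% "")
    if (!cls %in% c("tumor", "epidermis")) next
    if (f$geometry$type != "Polygon")
      mbFormatError("feature '%s' is not a Polygon", cls)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(p[1:2])))
    polys[[cls]] <- c(polys[[cls]], list(ring))
  }
  for (cls in c("tumor", "epidermis")) {
    if (length(polys[[cls]]) != 1L)
      mbFormatError("annotation must contain exactly one '%s' polygon (found %d)",
                    cls, length(polys[[cls]]))
  }
  tum <- openRing(polys$tumor[[1]]); epi <- openRing(polys$epidermis[[1]])
  for (nm in c("tumor", "epidermis")) {
    p <- if (nm == "tumor") tum else epi
    if (polygonAreaUm2(p) <= 0)
      mbValidationError("'%s' polygon has zero area", nm)
    if (!ringIsSimple(p))
      mbValidationError("'%s' polygon is self-intersecting", nm)
  }
  list(slide_id = slideId %||% sub("\\.[^.]*$", "", basename(path)),
       tumor = tum, epidermis = epi,
       pixel_size_um = js$properties$pixel_size_um %||% NA_real_)
}

#' @rdname readAnnotation
#' @param annotation annotation list to write.
#' @export
writeAnnotation <- function(annotation, path) {
  fc <- list(type = "FeatureCollection",
             properties = list(slide_id = annotation$slide_id,
                               pixel_size_um = annotation$pixel_size_um),
             features = list(
               geojsonPolygonFeature(annotation$tumor, "tumor"),
               geojsonPolygonFeature(annotation$epidermis, "epidermis")))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a clinical table
#'
#' Requires columns patient_id, age, mitosis, thickness, time, event,
#' endpoint; `event` may be logical or 0/1. Rejects duplicate patient ids,
#' negative times, non-positive ages or thicknesses.
#'
#' @param path CSV path.
#' @return validated data.frame (empty, with a warning, for an empty file).
#' @export
readClinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age", "mitosis", "thickness", "time", "event", "endpoint")
  missing <- setdiff(need, names(df))
  if (length(missing))
    mbFormatError("clinical table missing column(s): %s",
                  paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("clinical table '", basename(path), "' is empty")
    return(df)
  }
  if (anyDuplicated(df$patient_id))
    mbValidationError("duplicate patient_id: %s",
                      paste(unique(df$patient_id[duplicated(df$patient_id)]),
                            collapse = ", "))
  df$event <- as.logical(df$event)
  if (any(df$time < 0)) mbValidationError("negative survival time (row %d)",
                                          which(df$time < 0)[1])
  if (any(df$age <= 0)) mbValidationError("non-positive age (row %d)",
                                          which(df$age <= 0)[1])
  if (any(df$thickness <= 0)) mbValidationError("non-positive thickness (row %d)",
                                                which(df$thickness <= 0)[1])
  df
}

#' @rdname readClinical
#' @param clinical clinical data.frame to write.
#' @export
writeClinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}

configHash <- function(object) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(object, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

provenanceBlock <- function(seed = NULL, config = NULL) {
  list(package = "melbands",
       version = as.character(utils::packageVersion("melbands")),
       seed = seed,
       config_hash = if (!is.null(config)) configHash(config) else NULL)
}

#' Serialize / read a fitted marker gate (JSON)
#'
#' @param gate a [MarkerGate-class].
#' @param path JSON path.
#' @return `readGate` returns the reconstructed [MarkerGate-class].
#' @export
writeGate <- function(gate, path) {
  o <- gate@otsu; m <- gate@mixture
  jsonlite::write_json(list(
    slide_id = gate@slideId, marker = gate@marker,
    compartment = gate@compartment,
    failed = gate@failed, failure_reason = gate@failureReason,
    otsu = list(threshold = o@threshold, omega0 = o@omega0, omega1 = o@omega1,
                mu0 = o@mu0, mu1 = o@mu1, between_var = o@betweenVar,
                n_bins = o@nBins, bin_range = o@binRange),
    mixture = list(weights = m@weights, means = m@means, sds = m@sds,
                   n_iter = m@nIter, converged = m@converged),
    log_threshold = gate@logThreshold,
    final_threshold = gate@finalThreshold,
    positive_component = gate@positiveComponent,
    fallback_used = gate@fallbackUsed,
    foreground_unimodal = gate@foregroundUnimodal,
    n_cells = gate@nCells, n_foreground = gate@nForeground,
    n_dropped_nonpositive = gate@nDroppedNonpositive,
    provenance = provenanceBlock()),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeGate
#' @export
readGate <- function(path) {
  j <- jsonlite::fromJSON(path)
  otsu <- new("OtsuSplit",
              threshold = j$otsu$threshold %||% NA_real_,
              omega0 = j$otsu$omega0, omega1 = j$otsu$omega1,
              mu0 = j$otsu$mu0 %||% NA_real_, mu1 = j$otsu$mu1 %||% NA_real_,
              betweenVar = j$otsu$between_var %||% NA_real_,
              nBins = as.integer(j$otsu$n_bins),
              binRange = as.numeric(j$otsu$bin_range %||% c(NA, NA)))
  mix <- new("LogMixture", weights = j$mixture$weights, means = j$mixture$means,
             sds = j$mixture$sds, nIter = as.integer(j$mixture$n_iter),
             converged = j$mixture$converged, objective = numeric(0))
  new("MarkerGate", slideId = j$slide_id, marker = j$marker,
      compartment = j$compartment, otsu = otsu, mixture = mix,
      logThreshold = j$log_threshold %||% NA_real_,
      finalThreshold = j$final_threshold %||% NA_real_,
      positiveComponent = as.integer(j$positive_component %||% NA),
      fallbackUsed = j$fallback_used,
      foregroundUnimodal = j$foreground_unimodal %||% FALSE,
      failed = j$failed,
      failureReason = j$failure_reason %||% "",
      nCells = as.integer(j$n_cells), nForeground = as.integer(j$n_foreground),
      nDroppedNonpositive = as.integer(j$n_dropped_nonpositive %||% 0))
}

#' Write a fitted Cox model (JSON) or a result table (CSV)
#'
#' @param result a [CoxModelResult-class].
#' @param path output path.
#' @export
writeCoxResult <- function(result, path) {
  jsonlite::write_json(list(
    model_id = result@modelId, ties = result@tiesMethod,
    n = result@n, n_events = result@nEvents,
    log_partial_likelihood = result@logLik,
    terms = result@table,
    concordance = result@concordance, concordance_ci = result@concordanceCI,
    loocv_concordance = result@loocvC, loocv_ci = result@loocvCI,
    converged = result@converged,
    provenance = provenanceBlock()),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a slide simulation bundle to disk
#'
#' Writes the detection-dialect cell table, the annotation GeoJSON, and the
#' latent-truth sidecar as three separate files; the sidecar never shares a
#' file with the primary cell table.
#'
#' @param sim result of [simulateSlide()].
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
writeSlideBundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- sim$annotation$slide_id
  paths <- c(cells = file.path(dir, paste0(id, "_cells.csv")),
             annotation = file.path(dir, paste0(id, "_annotation.geojson")),
             truth = file.path(dir, paste0(id, "_truth.csv")))
  writeCellTable(sim$cells, paths["cells"])
  writeAnnotation(sim$annotation, paths["annotation"])
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  paths
}
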