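# Per-patient prognostic factor assembly: cell categories, per-band counts,
# densities and mean nucleus sizes, combined with the clinical factors.

#' Classify cells into the three analysis categories
#'
#' Using the gated positivity flags: *total* = every in-tumor cell, *tumor* =
#' S100-positive cells, *colocalized* = cells dually positive for S100 and
#' Ki67 (proliferating tumor cells). Cells with band `"outside"` are excluded
#' from all categories.
#'
#' @param cells data.frame carrying logical columns `ki67_pos` and `s100_pos`
#'   (and optionally `band`; without it all cells count as in-tumor).
#' @return `cells` with logical columns `cat_total`, `cat_tumor`, `cat_coloc`.
#' @export
classifyCategories <- function(cells) {
  need <- c("ki67_pos", "s100_pos")
  if (!all(need %in% names(cells)))
    mbValidationError("marker positivity flags missing (run gating first): %s",
                      paste(setdiff(need, names(cells)), collapse = ", "))
  inTumor <- if ("band" %in% names(cells)) cells$band != "outside"
             else rep(TRUE, nrow(cells))
  cells$cat_total <- inTumor
  cells$cat_tumor <- inTumor & cells$s100_pos
  cells$cat_coloc <- inTumor & cells$s100_pos & cells$ki67_pos
  cells
}

bandLevels <- c("superficial", "middle", "invasive")

#' Per-band counts, densities and mean nucleus sizes per category
#'
#' For each band (plus an `overall` row for the whole tumor): counts per
#' category, densities in cells/mm² using the raster band areas (the overall
#' row uses their sum), and arithmetic mean nucleus areas per category. An
#' empty category within a band yields a missing mean size — not zero — with
#' a warning.
#'
#' @param cells band-annotated, category-classified cells (see
#'   [annotateCells()], [classifyCategories()]).
#' @param geometry the slide's [BandGeometry-class].
#' @return data.frame, one row per band plus `overall`; columns `band`,
#'   `area_mm2`, then `n_`, `density_`, `mean_size_` for categories total,
#'   tumor, coloc.
#' @export
bandAggregates <- function(cells, geometry) {
  stopifnot(is(geometry, "BandGeometry"))
  if (!all(c("cat_total", "cat_tumor", "cat_coloc") %in% names(cells)))
    mbValidationError("cells lack category flags (run classifyCategories first)")
  if (!"band" %in% names(cells))
    mbValidationError("cells lack band labels (run annotateCells first)")
  areas <- geometry@bandAreasMm2
  if (any(areas <= 0)) mbGeometryError("zero band area")
  rows <- lapply(c(bandLevels, "overall"), function(b) {
    inBand <- if (b == "overall") cells$band != "outside" else cells$band == b
    area <- if (b == "overall") sum(areas) else areas[[b]]
    row <- list(band = b, area_mm2 = area)
    for (cat in c("total", "tumor", "coloc")) {
      sel <- inBand & cells[[paste0("cat_", cat)]]
      n <- sum(sel)
      row[[paste0("n_", cat)]] <- n
      row[[paste0("density_", cat)]] <- n / area
      if (n == 0L) {
        warning(sprintf("band '%s': no %s cells; mean nucleus size is missing",
                        b, cat), call. = FALSE)
        row[[paste0("mean_size_", cat)]] <- NA_real_
      } else {
        row[[paste0("mean_size_", cat)]] <- mean(cells$nucleus_area_um2[sel])
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble the per-patient prognostic factor vector
#'
#' Combines one patient's clinical record, band aggregates and geometry into
#' the full factor set: mitosis, thickness (mm, clinical Breslow), estimated
#' thickness (mm, from the PCA geometry), age, and per band (invasive,
#' middle, superficial, overall) the cell density, colocalized cell density,
#' colocalized-to-total and colocalized-to-tumor ratios, and the mean nucleus
#' sizes of all cells, tumor cells and colocalized cells. Ratios with a zero
#' denominator are missing, not zero.
#'
#' @param clinicalRow one-row data.frame with patient_id, age, mitosis,
#'   thickness.
#' @param aggregates output of [bandAggregates()].
#' @param geometry the slide's [BandGeometry-class].
#' @return one-row data.frame of features.
#' @export
assembleFeatures <- function(clinicalRow, aggregates, geometry) {
  stopifnot(nrow(clinicalRow) == 1L)
  out <- data.frame(patient_id = clinicalRow$patient_id,
                    mitosis = clinicalRow$mitosis,
                    thickness = clinicalRow$thickness,
                    estimated_thickness = thicknessMm(geometry),
                    age = clinicalRow$age,
                    stringsAsFactors = FALSE)
  for (b in c("invasive", "middle", "superficial", "overall")) {
    a <- aggregates[aggregates$band == b, ]
    rat <- function(num, den) if (den > 0) num / den else NA_real_
    out[[paste0("cell_density_", b)]] <- a$density_total
    out[[paste0("coloc_density_", b)]] <- a$density_coloc
    out[[paste0("coloc_total_ratio_", b)]] <- rat(a$n_coloc, a$n_total)
    out[[paste0("coloc_tumor_ratio_", b)]] <- rat(a$n_coloc, a$n_tumor)
    out[[paste0("nuclei_size_", b)]] <- a$mean_size_total
    out[[paste0("tumor_nuclei_size_", b)]] <- a$mean_size_tumor
    out[[paste0("coloc_nuclei_size_", b)]] <- a$mean_size_coloc
  }
  out
}

#' Human-readable labels for the prognostic factors
#'
#' @return named character vector mapping feature column names to the labels
#'   used in tables and figures (e.g. `nuclei_size_invasive` to
#'   "Invasive Band: Nuclei Size").
#' @export
factorDictionary <- function() {
  lab <- c(mitosis = "Mitosis (HPF)", thickness = "Thickness (mm)",
           estimated_thickness = "Estimated Thickness (mm)", age = "Age")
  bandLab <- c(invasive = "Invasive Band", middle = "Middle Band",
               superficial = "Superficial Band", overall = "Overall")
  kinds <- c(cell_density = "Cell Density",
             coloc_density = "Colocalized Cell Density",
             coloc_total_ratio = "Colocalized-to-Total Cell Ratio",
             coloc_tumor_ratio = "Colocalized-to-Tumor Cell Ratio",
             nuclei_size = "Nuclei Size",
             tumor_nuclei_size = "Tumor Cell Nuclei Size",
             coloc_nuclei_size = "Colocalized Cell Nuclei Size")
  for (k in names(kinds)) for (b in names(bandLab)) {
    lab[paste(k, b, sep = "_")] <- sprintf("%s: %s", bandLab[[b]], kinds[[k]])
  }
  lab
}
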