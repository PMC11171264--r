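# Synthetic slide and cohort generator. Emulates the three inputs the
# pipeline consumes — detection-style cell tables, tumor/epidermis
# annotations, and a clinical table with survival outcomes — with retained
# latent truth so every downstream stage can be checked against the
# generating values.

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Configuration for a synthetic mIHC slide
#'
#' Defines the geometry, cell density, per-marker two-component log-normal
#' intensity mixtures, and band-dependent nucleus-size shifts of a simulated
#' slide. Defaults: a 3 mm deep by 6 mm wide rectangular tumor with a 0.3 mm
#' epidermis strip on its superficial edge, 200 cells/mm², markers whose
#' positive and negative log-intensity components are separated by 4 standard
#' deviations (a clean but not trivial gating problem), mean nucleus area
#' 40 µm² with no band shift.
#'
#' @param tumor_shape "rectangle" (exact fixtures) or "blob" (smoothed random
#'   radial polygon).
#' @param tumor_depth_mm,tumor_width_mm,epidermis_band_mm geometry, mm.
#' @param cell_density_per_mm2 expected cells per mm² of tumor.
#' @param marker_mix named list per marker with `bg_log_mean`, `bg_log_sd`,
#'   `fg_log_mean`, `fg_log_sd`, `fg_fraction` (strictly in (0, 1); foreground
#'   log-mean must exceed the background log-mean), plus the dark noise floor
#'   of detection exports: `noise_fraction` (share of *negative* cells whose
#'   measured intensity is detector noise rather than autofluorescence),
#'   `noise_log_mean`, `noise_log_sd`. With the defaults the overall log
#'   distribution has a noise mode, a dim negative mode and a bright positive
#'   mode, so the Otsu phase strips the noise floor and the foreground that
#'   reaches the mixture phase is itself bimodal — the structure the two-phase
#'   gate is designed for.
#' @param nucleus_area_base_um2 mean nucleus area, µm².
#' @param nucleus_area_band_shift_um2 named numeric additive shift of the mean
#'   nucleus area per band (superficial, middle, invasive).
#' @param nucleus_area_sd_um2 nucleus-area standard deviation, µm².
#' @param seed integer RNG seed; all draws flow from a single RNG seeded once.
#' @return a validated list of class `SlideSimConfig`.
#' @export
slideSimConfig <- function(tumor_shape = c("rectangle", "blob"),
                           tumor_depth_mm = 3, tumor_width_mm = 6,
                           epidermis_band_mm = 0.3,
                           cell_density_per_mm2 = 200,
                           marker_mix = defaultMarkerMix(),
                           nucleus_area_base_um2 = 40,
                           nucleus_area_band_shift_um2 = c(
                             superficial = 0, middle = 0, invasive = 0),
                           nucleus_area_sd_um2 = 8,
                           seed = 1L) {
  tumor_shape <- match.arg(tumor_shape)
  sizes <- c(tumor_depth_mm, tumor_width_mm, epidermis_band_mm,
             cell_density_per_mm2, nucleus_area_base_um2, nucleus_area_sd_um2)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    mbConfigError("all slide size/density parameters must be positive")
  for (m in names(marker_mix)) {
    mm <- marker_mix[[m]]
    if (mm$fg_log_mean <= mm$bg_log_mean)
      mbConfigError("marker '%s': fg_log_mean must exceed bg_log_mean", m)
    if (mm$fg_fraction <= 0 || mm$fg_fraction >= 1)
      mbConfigError("marker '%s': fg_fraction must lie strictly in (0, 1)", m)
    if (mm$bg_log_sd <= 0 || mm$fg_log_sd <= 0)
      mbConfigError("marker '%s': log-sds must be positive", m)
    nf <- mm$noise_fraction %||% 0
    if (nf < 0 || nf >= 1)
      mbConfigError("marker '%s': noise_fraction must lie in [0, 1)", m)
    if (nf > 0 && (mm$noise_log_mean %||% -Inf) >= mm$bg_log_mean)
      mbConfigError("marker '%s': noise_log_mean must lie below bg_log_mean", m)
  }
  need <- c("superficial", "middle", "invasive")
  if (!all(need %in% names(nucleus_area_band_shift_um2)))
    mbConfigError("nucleus_area_band_shift_um2 must name superficial, middle, invasive")
  structure(list(
    tumor_shape = tumor_shape, tumor_depth_mm = tumor_depth_mm,
    tumor_width_mm = tumor_width_mm, epidermis_band_mm = epidermis_band_mm,
    cell_density_per_mm2 = cell_density_per_mm2, marker_mix = marker_mix,
    nucleus_area_base_um2 = nucleus_area_base_um2,
    nucleus_area_band_shift_um2 = nucleus_area_band_shift_um2[need],
    nucleus_area_sd_um2 = nucleus_area_sd_um2, seed = as.integer(seed)),
    class = "SlideSimConfig")
}

#' @rdname slideSimConfig
#' @param separation_sd separation of foreground and background log-means in
#'   units of the (common) log-sd.
#' @export
defaultMarkerMix <- function(separation_sd = 4) {
  mk <- function(frac) list(bg_log_mean = 3, bg_log_sd = 0.5,
                            fg_log_mean = 3 + separation_sd * 0.5,
                            fg_log_sd = 0.5, fg_fraction = frac,
                            noise_fraction = 0.5, noise_log_mean = 0,
                            noise_log_sd = 0.5)
  list(dapi = mk(0.99), ki67 = mk(0.30), s100 = mk(0.70))
}

blobPolygon <- function(depthUm, widthUm, nVert = 72L) {
  # smoothed random radial polygon with the requested depth/width extents
  th <- seq(0, 2 * pi, length.out = nVert + 1L)[-(nVert + 1L)]
  pert <- rep(0, nVert)
  for (k in 2:4) pert <- pert + stats::rnorm(1, 0, 0.08) * cos(k * th) +
      stats::rnorm(1, 0, 0.08) * sin(k * th)
  r <- 1 + pert - min(pert) * 0  # keep positive; pert is small
  x <- r * cos(th); y <- r * sin(th)
  x <- (x - min(x)) / (max(x) - min(x)) * widthUm
  y <- (y - min(y)) / (max(y) - min(y)) * depthUm
  cbind(x, y)
}

#' Simulate one mIHC slide: annotation, cell table and latent truth
#'
#' Cells are scattered uniformly inside the tumor polygon at the configured
#' density (Poisson total count). Each marker's intensity on its gated
#' compartment is drawn from a two-component log-normal mixture according to
#' a latent positivity label (Bernoulli `fg_fraction`); the remaining
#' compartment means are background draws. Nucleus areas are normal with a
#' band-dependent mean shift, truncated at 1 µm²; the true band comes from the
#' cell's true depth (vertical distance from the superficial edge) cut at
#' thirds of the tumor's depth extent. The latent truth (positivity labels,
#' depth, band) is returned as a separate sidecar table so pipeline code can
#' never consume it accidentally.
#'
#' @param config a [slideSimConfig()].
#' @param slideId slide identifier.
#' @return list with `annotation` (slide_id, tumor and epidermis polygon
#'   matrices in µm, pixel_size_um provenance), `cells` (detection-dialect
#'   data.frame) and `truth` (sidecar data.frame).
#' @export
simulateSlide <- function(config, slideId = "sim_slide") {
  stopifnot(inherits(config, "SlideSimConfig"))
  withSeed(config$seed, {
    D <- config$tumor_depth_mm * 1000
    W <- config$tumor_width_mm * 1000
    E <- config$epidermis_band_mm * 1000
    tumor <- if (config$tumor_shape == "rectangle") {
      cbind(c(0, W, W, 0), c(0, 0, D, D))
    } else blobPolygon(D, W)
    ymin <- min(tumor[, 2])
    epidermis <- cbind(c(0, W, W, 0), ymin + c(-E, -E, 0, 0))
    areaMm2 <- polygonAreaUm2(tumor) / 1e6
    n <- stats::rpois(1, config$cell_density_per_mm2 * areaMm2)
    if (config$tumor_shape == "rectangle") {
      xy <- cbind(stats::runif(n, 0, W), stats::runif(n, 0, D))
    } else {
      xy <- matrix(numeric(0), 0, 2)
      while (nrow(xy) < n) {
        m <- ceiling((n - nrow(xy)) * 1.6) + 10L
        cand <- cbind(stats::runif(m, min(tumor[, 1]), max(tumor[, 1])),
                      stats::runif(m, min(tumor[, 2]), max(tumor[, 2])))
        xy <- rbind(xy, cand[pointsInPolygon(cand, tumor), , drop = FALSE])
      }
      xy <- xy[seq_len(n), , drop = FALSE]
    }
    depth <- xy[, 2] - ymin
    Dext <- max(tumor[, 2]) - ymin
    band <- cut(depth, breaks = c(-Inf, Dext / 3, 2 * Dext / 3, Inf),
                labels = c("superficial", "middle", "invasive"), right = FALSE)
    shift <- config$nucleus_area_band_shift_um2[as.character(band)]
    area <- pmax(stats::rnorm(n, config$nucleus_area_base_um2 + shift,
                              config$nucleus_area_sd_um2), 1)
    cells <- data.frame(cell_id = sprintf("%s_c%05d", slideId, seq_len(n)),
                        slide_id = slideId,
                        centroid_x_um = xy[, 1], centroid_y_um = xy[, 2],
                        nucleus_area_um2 = area,
                        stringsAsFactors = FALSE)
    truth <- data.frame(cell_id = cells$cell_id,
                        true_depth_um = depth,
                        true_band = as.character(band),
                        stringsAsFactors = FALSE)
    comps <- c("nucleus", "cytoplasm", "membrane")
    for (m in names(config$marker_mix)) {
      mm <- config$marker_mix[[m]]
      pos <- stats::runif(n) < mm$fg_fraction
      nf <- mm$noise_fraction %||% 0
      isNoise <- !pos & stats::runif(n) < nf
      val <- stats::rlnorm(n, mm$bg_log_mean, mm$bg_log_sd)
      val[pos] <- stats::rlnorm(sum(pos), mm$fg_log_mean, mm$fg_log_sd)
      val[isNoise] <- stats::rlnorm(sum(isNoise), mm$noise_log_mean %||% 0,
                                    mm$noise_log_sd %||% 0.5)
      gatedComp <- defaultCompartment(m)
      for (cp in comps) {
        cells[[paste(m, cp, "mean", sep = "_")]] <-
          if (cp == gatedComp) val else stats::rlnorm(n, mm$bg_log_mean, mm$bg_log_sd)
      }
      truth[[paste0("true_", m)]] <- pos
    }
    list(annotation = list(slide_id = slideId, tumor = tumor,
                           epidermis = epidermis, pixel_size_um = 0.5),
         cells = cells, truth = truth)
  })
}

#' Configuration for a synthetic patient cohort
#'
#' Defines a Weibull proportional-hazards generative model: per-patient
#' features are independent normals, the linear predictor is the
#' beta-weighted sum of features, survival times follow a Weibull baseline
#' accelerated by `exp(lp)`, and censoring is independent exponential with its
#' rate calibrated so the expected censored fraction matches
#' `censoring_rate`. Times are in months.
#'
#' @param n_patients number of patients (>= 2).
#' @param beta named numeric, log-hazard per unit of each factor.
#' @param feature_means,feature_sds named numeric over the same factors.
#' @param baseline_hazard_scale,baseline_hazard_shape Weibull scale (months)
#'   and shape, both positive.
#' @param censoring_rate expected fraction censored, in [0, 1).
#' @param seed integer RNG seed.
#' @return a validated list of class `CohortSimConfig`.
#' @export
cohortSimConfig <- function(n_patients, beta,
                            feature_means = stats::setNames(rep(0, length(beta)), names(beta)),
                            feature_sds = stats::setNames(rep(1, length(beta)), names(beta)),
                            baseline_hazard_scale = 36,
                            baseline_hazard_shape = 1.2,
                            censoring_rate = 0.3, seed = 1L) {
  if (n_patients < 2) mbConfigError("n_patients must be >= 2")
  if (baseline_hazard_scale <= 0 || baseline_hazard_shape <= 0)
    mbConfigError("Weibull hazard parameters must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    mbConfigError("censoring_rate must lie in [0, 1)")
  if (is.null(names(beta)) || any(!nzchar(names(beta))))
    mbConfigError("beta must be a named vector")
  structure(list(n_patients = as.integer(n_patients), beta = beta,
                 feature_means = feature_means[names(beta)],
                 feature_sds = feature_sds[names(beta)],
                 baseline_hazard_scale = baseline_hazard_scale,
                 baseline_hazard_shape = baseline_hazard_shape,
                 censoring_rate = censoring_rate, seed = as.integer(seed)),
            class = "CohortSimConfig")
}

# Draw Weibull proportional-hazards survival with exponential censoring whose
# rate is calibrated (on the drawn event times) to the requested expected
# censored fraction. Consumes RNG; callers wrap in withSeed().
weibullPHSurvival <- function(lp, scale, shape, censoringRate) {
  n <- length(lp)
  u <- stats::runif(n)
  tEvent <- scale * (-log(u) / exp(lp))^(1 / shape)
  if (censoringRate == 0) {
    return(data.frame(time = tEvent, event = rep(TRUE, n),
                      event_time = tEvent, censor_time = rep(Inf, n)))
  }
  lam <- stats::uniroot(function(l) mean(1 - exp(-l * tEvent)) - censoringRate,
                        lower = 1e-12, upper = 1e6 / stats::median(tEvent),
                        extendInt = "upX", tol = 1e-12)$root
  tCens <- stats::rexp(n, lam)
  data.frame(time = pmin(tEvent, tCens), event = tEvent <= tCens,
             event_time = tEvent, censor_time = tCens)
}

#' Simulate a cohort of features and proportional-hazards survival outcomes
#'
#' @param config a [cohortSimConfig()].
#' @return list with `features` (patient_id + one column per factor),
#'   `survival` (patient_id, time, event) and `truth` (patient_id, the true
#'   linear predictor `lp`, the uncensored event time and the censoring time).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "CohortSimConfig"))
  withSeed(config$seed, {
    n <- config$n_patients
    fac <- names(config$beta)
    X <- sapply(fac, function(f)
      stats::rnorm(n, config$feature_means[[f]], config$feature_sds[[f]]))
    X <- matrix(X, nrow = n, dimnames = list(NULL, fac))
    lp <- as.numeric(X %*% config$beta)
    sv <- weibullPHSurvival(lp, config$baseline_hazard_scale,
                            config$baseline_hazard_shape, config$censoring_rate)
    pid <- sprintf("P%03d", seq_len(n))
    list(features = data.frame(patient_id = pid, X, stringsAsFactors = FALSE),
         survival = data.frame(patient_id = pid, time = sv$time,
                               event = sv$event, stringsAsFactors = FALSE),
         truth = data.frame(patient_id = pid, lp = lp,
                            event_time = sv$event_time,
                            censor_time = sv$censor_time,
                            stringsAsFactors = FALSE))
  })
}

#' Deterministic synthetic clinical table mirroring published cohort marginals
#'
#' Builds a 26-patient, two-endpoint clinical table whose marginals match the
#' cohort summary the method was originally reported on: median age 62.5
#' (range 24–78), 20 male / 6 female, 16 of 26 overall-survival events
#' (median OS 35.5 months), 18 of 26 progression-free-survival events (median
#' PFS 27.5 months). The table is entirely synthetic — it exists so the
#' cohort-summary arithmetic can be exercised — and is constructed
#' deterministically without randomness.
#'
#' @return list with elements `os` and `pfs`, each a clinical data.frame with
#'   columns patient_id, age, sex, mitosis, thickness, time, event, endpoint.
#' @export
tableTwoLikeClinical <- function() {
  n <- 26L
  pid <- sprintf("P%03d", seq_len(n))
  # sorted ages: min 24, max 78, 13th/14th average to 62.5
  age <- c(24, 31, 38, 42, 45, 48, 51, 54, 56, 58, 60, 61, 62, 63,
           64, 65, 66, 68, 69, 70, 71, 72, 73, 74, 76, 78)
  sex <- c(rep("male", 20), rep("female", 6))
  mitosis <- rep(c(1, 2, 3, 4, 5, 6, 8, 10, 12, 15, 2, 3, 7), length.out = n)
  thickness <- rep(c(1.3, 1.8, 2.2, 2.9, 3.5, 4.1, 5.0, 6.2, 2.5, 3.1,
                     1.6, 4.6, 7.3), length.out = n)
  mkTimes <- function(median, spread) {
    # 26 values with the requested median = mean of the 13th and 14th
    lo <- median - spread * (13:1) / 13
    hi <- median + spread * (1:13) / 13
    c(lo[1:12], median - spread / 26, median + spread / 26, hi[2:13])
  }
  osTime <- mkTimes(35.5, 30)
  pfsTime <- mkTimes(27.5, 24)
  osEvent <- rep(c(TRUE, FALSE), c(16L, 10L))
  pfsEvent <- rep(c(TRUE, FALSE), c(18L, 8L))
  base <- data.frame(patient_id = pid, age = age, sex = sex,
                     mitosis = mitosis, thickness = thickness,
                     stringsAsFactors = FALSE)
  list(os = cbind(base, data.frame(time = osTime, event = osEvent,
                                   endpoint = "OS", stringsAsFactors = FALSE)),
       pfs = cbind(base, data.frame(time = pfsTime, event = pfsEvent,
                                    endpoint = "PFS", stringsAsFactors = FALSE)))
}
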