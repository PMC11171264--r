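# Cox proportional-hazards evaluation layer: model fits (Breslow ties) with
# Wald HR/CI/p, Harrell's concordance with bootstrap percentile CIs, LOOCV
# concordance over pooled out-of-fold linear predictors, the univariable
# factor screen and the three-covariate multivariable models.

#' @importFrom survival coxph Surv concordance
NULL

buildCoxFrame <- function(data, covariates, timeCol, eventCol) {
  miss <- setdiff(c(timeCol, eventCol, covariates), names(data))
  if (length(miss))
    mbValidationError("missing column(s): %s", paste(miss, collapse = ", "))
  df <- data[c(timeCol, eventCol, covariates)]
  names(df)[1:2] <- c(".time", ".event")
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$.event <- as.logical(df$.event)
  df
}

checkDesign <- function(X) {
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    mbValidationError("constant covariate(s): %s",
                      paste(colnames(X)[sds == 0], collapse = ", "))
  if (ncol(X) > 1L) {
    r <- qr(scale(X))$rank
    if (r < ncol(X))
      mbValidationError("collinear covariates (design rank %d < %d)", r, ncol(X))
  }
  invisible(TRUE)
}

fitCoxph <- function(df, covariates, ties) {
  f <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                               paste(sprintf("`%s`", covariates), collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(f, data = df, ties = ties),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  list(fit = fit, clean = !warned)
}

#' Fit a Cox proportional-hazards model
#'
#' Breslow-ties partial-likelihood fit with Wald 95% confidence intervals and
#' two-sided Wald p-values per covariate, plus the apparent Harrell's
#' concordance of the fitted linear predictor. Rows with missing values in
#' the time, event or covariate columns are dropped (complete-case per
#' model). A monotone likelihood (perfect separation) is flagged as
#' non-convergence; constant or collinear covariates are rejected.
#'
#' @param data data.frame holding time, event and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param timeCol,eventCol column names (defaults "time", "event").
#' @param ties "breslow" (default) or "efron".
#' @param modelId label stored in the result.
#' @return a [CoxModelResult-class] (bootstrap/LOOCV CI slots NA; see
#'   [bootstrapConcordance()] and [loocvConcordance()]).
#' @export
coxFit <- function(data, covariates, timeCol = "time", eventCol = "event",
                   ties = c("breslow", "efron"), modelId = paste(covariates, collapse = "+")) {
  ties <- match.arg(ties)
  df <- buildCoxFrame(data, covariates, timeCol, eventCol)
  if (sum(df$.event) < 2L)
    mbValidationError("need at least 2 events (have %d)", sum(df$.event))
  checkDesign(as.matrix(df[covariates]))
  res <- fitCoxph(df, covariates, ties)
  fit <- res$fit
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  tab <- data.frame(term = covariates, beta = as.numeric(beta),
                    se = as.numeric(se), hr = exp(as.numeric(beta)),
                    lower = exp(as.numeric(beta) - z * se),
                    upper = exp(as.numeric(beta) + z * se),
                    p = 2 * stats::pnorm(-abs(as.numeric(beta) / se)),
                    stringsAsFactors = FALSE)
  lp <- as.numeric(as.matrix(df[covariates]) %*% beta)
  cidx <- harrellC(lp, df$.time, df$.event)
  new("CoxModelResult", modelId = modelId, table = tab,
      logLik = fit$loglik[2], n = nrow(df), nEvents = sum(df$.event),
      concordance = cidx, concordanceCI = c(NA_real_, NA_real_),
      loocvC = NA_real_, loocvCI = c(NA_real_, NA_real_),
      tiesMethod = ties, converged = res$clean)
}

#' Harrell's concordance index
#'
#' Over all comparable pairs — the strictly earlier time ends in an event —
#' the fraction of pairs where the higher risk score fails first, with tied
#' scores counted as half-concordant. Pairs with identical times are not
#' comparable under this convention (`survival::concordance` additionally
#' compares event-versus-censored pairs at tied times; on tie-free data the
#' two agree exactly).
#'
#' @param risk numeric risk scores (higher = worse prognosis).
#' @param time,event aligned survival times and event indicators.
#' @return concordance between 0 and 1.
#' @export
harrellC <- function(risk, time, event) {
  if (length(risk) != length(time) || length(time) != length(event))
    mbValidationError("risk, time and event must have equal length")
  event <- as.logical(event)
  # comparable pairs indexed by their earlier, event-bearing member i
  earlier <- outer(time, time, "<") & event
  if (!any(earlier))
    mbValidationError("no comparable pairs; concordance undefined")
  conc <- sum(earlier & outer(risk, risk, ">"))
  tied <- sum(earlier & outer(risk, risk, "=="))
  (conc + 0.5 * tied) / sum(earlier)
}

#' Bootstrap percentile confidence interval for Harrell's concordance
#'
#' Resamples patients with replacement, refits the Cox model on each
#' replicate and recomputes the concordance of the replicate's fitted linear
#' predictor on the replicate. Replicates with fewer than two events or a
#' failed fit are skipped (with a warning when more than 10% are).
#'
#' @param data,covariates,timeCol,eventCol,ties as in [coxFit()].
#' @param B number of bootstrap replicates (>= 100; default 1000).
#' @param seed RNG seed.
#' @return list with `concordance` (full-data apparent C), `ci`
#'   (percentile 2.5/97.5), `replicates` (the kept bootstrap C values) and
#'   `nSkipped`.
#' @export
bootstrapConcordance <- function(data, covariates, timeCol = "time",
                                 eventCol = "event", ties = "breslow",
                                 B = 1000L, seed = 1L) {
  if (B < 100L) mbConfigError("B must be >= 100")
  df <- buildCoxFrame(data, covariates, timeCol, eventCol)
  checkDesign(as.matrix(df[covariates]))
  full <- fitCoxph(df, covariates, ties)$fit
  lpFull <- as.numeric(as.matrix(df[covariates]) %*% stats::coef(full))
  cFull <- harrellC(lpFull, df$.time, df$.event)
  n <- nrow(df)
  reps <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      d <- df[idx, , drop = FALSE]
      if (sum(d$.event) < 2L) return(NA_real_)
      out <- tryCatch({
        fit <- fitCoxph(d, covariates, ties)$fit
        lp <- as.numeric(as.matrix(d[covariates]) %*% stats::coef(fit))
        harrellC(lp, d$.time, d$.event)
      }, error = function(e) NA_real_)
      out
    }, numeric(1))
  })
  skipped <- sum(is.na(reps))
  if (skipped > 0.1 * B)
    warning(sprintf("%d of %d bootstrap replicates skipped", skipped, B))
  keep <- reps[!is.na(reps)]
  list(concordance = cFull,
       ci = as.numeric(stats::quantile(keep, c(0.025, 0.975), names = FALSE)),
       replicates = keep, nSkipped = skipped)
}

#' Leave-one-out cross-validated concordance
#'
#' For each patient the model is refitted on the remaining n - 1 and the
#' held-out patient's (uncentred) linear predictor recorded; the pooled
#' out-of-fold predictors are scored with Harrell's C, and its CI obtained by
#' bootstrapping the pooled (predictor, time, event) triples. Folds whose
#' refit fails are skipped and counted.
#'
#' @param data,covariates,timeCol,eventCol,ties as in [coxFit()].
#' @param B bootstrap replicates for the CI (default 1000).
#' @param seed RNG seed for the CI bootstrap.
#' @return list with `concordance`, `ci`, `lp` (pooled out-of-fold
#'   predictors) and `nSkipped`.
#' @export
loocvConcordance <- function(data, covariates, timeCol = "time",
                             eventCol = "event", ties = "breslow",
                             B = 1000L, seed = 1L) {
  df <- buildCoxFrame(data, covariates, timeCol, eventCol)
  n <- nrow(df)
  if (n < 3L) mbValidationError("LOOCV needs at least 3 complete records")
  X <- as.matrix(df[covariates])
  lp <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    cf <- tryCatch(stats::coef(fitCoxph(df[-i, , drop = FALSE], covariates, ties)$fit),
                   error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) { skipped <- skipped + 1L; next }
    lp[i] <- sum(X[i, ] * cf)
  }
  ok <- !is.na(lp)
  cPooled <- harrellC(lp[ok], df$.time[ok], df$.event[ok])
  m <- sum(ok)
  reps <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(m, m, replace = TRUE)
      tryCatch(harrellC(lp[ok][idx], df$.time[ok][idx], df$.event[ok][idx]),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  keep <- reps[!is.na(reps)]
  list(concordance = cPooled,
       ci = as.numeric(stats::quantile(keep, c(0.025, 0.975), names = FALSE)),
       lp = lp, nSkipped = skipped)
}

#' Univariable Cox screen over a factor list
#'
#' One single-covariate Cox model per factor (complete-case per model), with
#' HR, Wald CI and p, and the factor's concordance with a bootstrap CI.
#' Factors missing for more than half the patients are excluded with a
#' warning. No multiple-testing correction is applied.
#'
#' @param data data.frame with time, event and factor columns.
#' @param factors character vector of factor column names.
#' @param timeCol,eventCol,ties as in [coxFit()].
#' @param B,seed bootstrap settings for the per-factor concordance CI.
#' @return data.frame with one row per screened factor: factor, label, n,
#'   n_events, hr, lower, upper, p, concordance, c_lower, c_upper.
#' @export
univariateScreen <- function(data, factors, timeCol = "time", eventCol = "event",
                             ties = "breslow", B = 1000L, seed = 1L) {
  dict <- factorDictionary()
  rows <- list()
  for (k in seq_along(factors)) {
    f <- factors[k]
    if (!f %in% names(data)) {
      warning(sprintf("factor '%s' absent from the feature table; skipped", f))
      next
    }
    if (mean(is.na(data[[f]])) > 0.5) {
      warning(sprintf("factor '%s' missing for >50%% of patients; excluded", f))
      next
    }
    res <- tryCatch(coxFit(data, f, timeCol, eventCol, ties = ties, modelId = f),
                    melbands_error = function(e) e)
    if (inherits(res, "condition")) {
      warning(sprintf("factor '%s': %s; excluded", f, conditionMessage(res)))
      next
    }
    # per-factor seed derives from the factor name, not its list position,
    # so screens over permuted factor lists are identical row-for-row
    fseed <- (seed + sum(utf8ToInt(f) * seq_along(utf8ToInt(f)))) %% 2147483647L
    bs <- bootstrapConcordance(data, f, timeCol, eventCol, ties,
                               B = B, seed = fseed)
    tab <- res@table
    lb <- unname(dict[f]); if (is.na(lb)) lb <- f
    rows[[f]] <- data.frame(
      factor = f, label = lb, n = res@n, n_events = res@nEvents,
      hr = tab$hr, lower = tab$lower, upper = tab$upper, p = tab$p,
      concordance = bs$concordance, c_lower = bs$ci[1], c_upper = bs$ci[2],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multivariable Cox models: traditional factors plus one nuclei-size factor
#'
#' Fits the base model (mitosis + thickness) and one three-covariate model
#' per invasive-band nuclei-size factor (all cells, tumor cells, colocalized
#' cells), each on complete cases, with apparent concordance (bootstrap CI)
#' and LOOCV concordance (bootstrap CI over pooled out-of-fold predictors).
#'
#' @param data feature table with time and event columns.
#' @param baseFactors the traditional covariates (default mitosis, thickness).
#' @param sizeFactors the nuclei-size factors to add one at a time.
#' @param timeCol,eventCol,ties as in [coxFit()].
#' @param B,seed bootstrap settings.
#' @param loocv compute the LOOCV concordance (default TRUE).
#' @return named list of [CoxModelResult-class] ("base" first).
#' @export
multivariableModels <- function(data,
                                baseFactors = c("mitosis", "thickness"),
                                sizeFactors = c("nuclei_size_invasive",
                                                "tumor_nuclei_size_invasive",
                                                "coloc_nuclei_size_invasive"),
                                timeCol = "time", eventCol = "event",
                                ties = "breslow", B = 1000L, seed = 1L,
                                loocv = TRUE) {
  specs <- c(list(base = baseFactors),
             stats::setNames(lapply(sizeFactors, function(f) c(f, baseFactors)),
                             sizeFactors))
  out <- list()
  for (k in seq_along(specs)) {
    nm <- names(specs)[k]
    cov <- specs[[k]]
    res <- coxFit(data, cov, timeCol, eventCol, ties = ties, modelId = nm)
    bs <- bootstrapConcordance(data, cov, timeCol, eventCol, ties,
                               B = B, seed = seed + 100L * k)
    res@concordanceCI <- bs$ci
    if (loocv) {
      lo <- loocvConcordance(data, cov, timeCol, eventCol, ties,
                             B = B, seed = seed + 100L * k + 1L)
      res@loocvC <- lo$concordance
      res@loocvCI <- lo$ci
    }
    out[[nm]] <- res
  }
  out
}

#' Tabulate a list of fitted multivariable models
#'
#' @param models named list of [CoxModelResult-class] (see
#'   [multivariableModels()]).
#' @return data.frame in the published table layout: one row per covariate
#'   per model with HR, CI bounds, p, and the model's apparent and LOOCV
#'   C-indices with CIs on the model's first row.
#' @export
coxModelTable <- function(models) {
  dict <- factorDictionary()
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    tab <- m@table
    lb <- unname(dict[tab$term]); lb[is.na(lb)] <- tab$term[is.na(lb)]
    data.frame(model = nm, term = tab$term,
               label = lb,
               hr = tab$hr, lower = tab$lower, upper = tab$upper, p = tab$p,
               n = m@n,
               c_index = c(m@concordance, rep(NA, nrow(tab) - 1L)),
               c_lower = c(m@concordanceCI[1], rep(NA, nrow(tab) - 1L)),
               c_upper = c(m@concordanceCI[2], rep(NA, nrow(tab) - 1L)),
               loocv_c = c(m@loocvC, rep(NA, nrow(tab) - 1L)),
               loocv_lower = c(m@loocvCI[1], rep(NA, nrow(tab) - 1L)),
               loocv_upper = c(m@loocvCI[2], rep(NA, nrow(tab) - 1L)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize the clinical characteristics of a cohort
#'
#' Median age and range, sex counts with percentages, and per endpoint the
#' event count, event percentage and median follow-up time. Percentages are
#' rounded to one decimal.
#'
#' @param ... one or more clinical data.frames (each a single endpoint; see
#'   [readClinical()]), or a single list of them.
#' @return list of class `CohortSummary`: n, median_age, age_range, sex
#'   (data.frame or NULL), endpoints (named list with n_event, event_pct,
#'   median_time).
#' @export
summarizeCohort <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]]))
    tabs <- tabs[[1]]
  if (!length(tabs)) mbValidationError("need at least one clinical table")
  first <- tabs[[1]]
  if (nrow(first) < 1L) mbValidationError("clinical table is empty")
  out <- list(n = nrow(first),
              median_age = stats::median(first$age),
              age_range = range(first$age))
  if ("sex" %in% names(first)) {
    tb <- table(first$sex)
    out$sex <- data.frame(sex = names(tb), n = as.integer(tb),
                          pct = round(100 * as.integer(tb) / sum(tb), 1),
                          stringsAsFactors = FALSE)
  }
  out$endpoints <- list()
  for (tab in tabs) {
    ep <- as.character(tab$endpoint[1])
    ev <- as.logical(tab$event)
    out$endpoints[[ep]] <- list(
      n_event = sum(ev),
      event_pct = round(100 * sum(ev) / nrow(tab), 1),
      censored_pct = round(100 * sum(!ev) / nrow(tab), 1),
      median_time = stats::median(tab$time))
  }
  class(out) <- "CohortSummary"
  out
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("Cohort: n = %d; median age %.1f (range %g-%g)\n",
              x$n, x$median_age, x$age_range[1], x$age_range[2]))
  if (!is.null(x$sex))
    for (i in seq_len(nrow(x$sex)))
      cat(sprintf("  %s: %d (%.1f%%)\n", x$sex$sex[i], x$sex$n[i], x$sex$pct[i]))
  for (ep in names(x$endpoints)) {
    e <- x$endpoints[[ep]]
    cat(sprintf("  %s: %d events (%.1f%%), median time %.1f months\n",
                ep, e$n_event, e$event_pct, e$median_time))
  }
  invisible(x)
}
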