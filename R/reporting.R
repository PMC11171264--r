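# Correlation analysis, publication-style figures, and the end-to-end
# pipeline driver.

#' Significance stars for p-values
#'
#' Pure threshold map: "***" for p < 0.001, "**" for p < 0.01, "*" for
#' p < 0.05, "" otherwise (strict inequalities).
#'
#' @param p numeric vector of p-values.
#' @return character vector of star annotations.
#' @export
significanceStars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

#' Pairwise correlation matrix with significance stars
#'
#' Pairwise complete-case correlations among the selected factors, two-sided
#' p-values from the t-distribution transform of r, and star annotations at
#' the 0.05/0.01/0.001 levels. Constant factors (or pairs with fewer than 3
#' complete observations) get missing entries with a warning.
#'
#' @param data feature data.frame.
#' @param factors character vector of factor columns.
#' @param method "pearson" (default) or "spearman".
#' @return list of class `melbandsCorrelation` with matrices `r`, `p`,
#'   `stars`, `n` and the `method`.
#' @export
correlationMatrix <- function(data, factors, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  miss <- setdiff(factors, names(data))
  if (length(miss))
    mbValidationError("factor(s) absent: %s", paste(miss, collapse = ", "))
  k <- length(factors)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(factors, factors))
  const <- vapply(factors, function(f) {
    v <- data[[f]][!is.na(data[[f]])]
    length(v) < 2L || stats::sd(v) == 0
  }, logical(1))
  if (any(const))
    warning("constant factor(s) set to missing: ",
            paste(factors[const], collapse = ", "))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j < i) next
      x <- data[[factors[i]]]; y <- data[[factors[j]]]
      ok <- !is.na(x) & !is.na(y)
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (i == j) {
        if (!const[i]) { r[i, i] <- 1; p[i, i] <- 0 }
        next
      }
      if (const[i] || const[j] || sum(ok) < 3L) next
      ct <- stats::cor.test(x[ok], y[ok], method = method, exact = FALSE)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- matrix(significanceStars(p), k, k, dimnames = dimnames(p))
  structure(list(r = r, p = p, stars = stars, n = nmat, method = method),
            class = "melbandsCorrelation")
}

#' @export
print.melbandsCorrelation <- function(x, ...) {
  cat(sprintf("Correlation matrix (%s), %d factors\n", x$method, ncol(x$r)))
  disp <- matrix(sprintf("%.2f%s", x$r, x$stars), nrow(x$r),
                 dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "."
  print(disp, quote = FALSE)
  invisible(x)
}

#' @rdname correlationMatrix
#' @param x a `melbandsCorrelation`.
#' @param path CSV output path.
#' @export
writeCorrelation <- function(x, path) {
  long <- expand.grid(factor_a = rownames(x$r), factor_b = colnames(x$r),
                      stringsAsFactors = FALSE)
  long$r <- as.numeric(x$r)
  long$p <- as.numeric(x$p)
  long$stars <- as.character(x$stars)
  long$n <- as.numeric(x$n)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

# ---- figures (side artifacts; every plotted number also lands in a CSV) ----

#' Diagnostic histogram of a fitted gate
#'
#' Log-scale histogram of the foreground (T1) intensities overlaid with the
#' two weighted Gaussian components, their sum, and the intersection
#' threshold.
#'
#' @param gate a [MarkerGate-class].
#' @param values the intensities the gate was fitted on (linear scale).
#' @param bins histogram bins.
#' @return a ggplot object.
#' @export
plotGateHistogram <- function(gate, values, bins = 80) {
  if (gate@failed) mbGatingError("cannot plot a failed gate")
  lv <- log(values[values > 0])
  fg <- lv[lv > gate@otsu@threshold]
  m <- gate@mixture
  xs <- seq(min(fg), max(fg), length.out = 400)
  dens <- data.frame(
    x = rep(xs, 3),
    y = c(m@weights[1] * stats::dnorm(xs, m@means[1], m@sds[1]),
          m@weights[2] * stats::dnorm(xs, m@means[2], m@sds[2]),
          m@weights[1] * stats::dnorm(xs, m@means[1], m@sds[1]) +
            m@weights[2] * stats::dnorm(xs, m@means[2], m@sds[2])),
    curve = rep(c("component 1", "component 2", "mixture"), each = length(xs)))
  ggplot2::ggplot() +
    ggplot2::geom_histogram(data = data.frame(x = fg),
                            ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
                            bins = bins, fill = "gold", colour = "grey40") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$curve)) +
    ggplot2::geom_vline(xintercept = gate@logThreshold,
                        linetype = "dashed", colour = "darkgreen") +
    ggplot2::labs(x = sprintf("log %s (%s mean)", gate@marker, gate@compartment),
                  y = "density",
                  title = sprintf("%s: %s gate (threshold %.3g)",
                                  gate@slideId, gate@marker, gate@finalThreshold)) +
    ggplot2::theme_minimal()
}

#' Band overlay plot of a slide
#'
#' The tumor raster coloured by band, the invasive-margin polyline, and
#' (optionally) cell centroids coloured by marker positivity.
#'
#' @param geometry a [BandGeometry-class].
#' @param cells optional annotated, gated cell table.
#' @return a ggplot object.
#' @export
plotBandOverlay <- function(geometry, cells = NULL) {
  res <- geometry@rasterRes; org <- geometry@rasterOrigin
  nx <- nrow(geometry@bandRaster); ny <- ncol(geometry@bandRaster)
  df <- data.frame(
    x = org[1] + (rep(seq_len(nx), times = ny) - 1) * res,
    y = org[2] + (rep(seq_len(ny), each = nx) - 1) * res,
    band = factor(c("superficial", "middle", "invasive")[as.vector(geometry@bandRaster)],
                  levels = c("superficial", "middle", "invasive")))
  df <- df[!is.na(df$band), ]
  mar <- as.data.frame(geometry@margin)
  names(mar) <- c("x", "y")
  g <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = df, ggplot2::aes(x = .data$x, y = .data$y,
                                                 fill = .data$band)) +
    ggplot2::scale_fill_manual(values = c(superficial = "grey95",
                                          middle = "steelblue1",
                                          invasive = "steelblue4")) +
    ggplot2::geom_path(data = mar, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "magenta", linewidth = 1) +
    ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::labs(title = geometry@slideId, x = "x (um)", y = "y (um, depth)") +
    ggplot2::theme_minimal()
  if (!is.null(cells) && all(c("ki67_pos", "s100_pos") %in% names(cells))) {
    cells$call <- ifelse(cells$s100_pos & cells$ki67_pos, "colocalized",
                         ifelse(cells$s100_pos, "S100+",
                                ifelse(cells$ki67_pos, "Ki67+", "negative")))
    g <- g + ggplot2::geom_point(
      data = cells,
      ggplot2::aes(x = .data$centroid_x_um, y = .data$centroid_y_um,
                   colour = .data$call), size = 0.3, alpha = 0.6)
  }
  g
}

#' Boxplots of nucleus sizes across bands
#'
#' @param cells annotated, category-classified cell table (possibly pooled
#'   over slides).
#' @return a ggplot object.
#' @export
plotNucleiBoxplots <- function(cells) {
  keep <- cells$band %in% bandLevels
  sub <- cells[keep, ]
  long <- rbind(
    data.frame(band = sub$band, size = sub$nucleus_area_um2,
               category = "all cells")[sub$cat_total, ],
    data.frame(band = sub$band, size = sub$nucleus_area_um2,
               category = "tumor cells")[sub$cat_tumor, ],
    data.frame(band = sub$band, size = sub$nucleus_area_um2,
               category = "colocalized cells")[sub$cat_coloc, ])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$band, y = .data$size)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(x = NULL, y = "nucleus area (um^2)") +
    ggplot2::theme_minimal()
}

#' Forest plot of per-factor concordance indices
#'
#' @param screen result of [univariateScreen()].
#' @return a ggplot object.
#' @export
plotConcordanceForest <- function(screen) {
  screen$label <- factor(screen$label, levels = rev(screen$label))
  ggplot2::ggplot(screen, ggplot2::aes(x = .data$concordance, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$c_lower,
                                         xmax = .data$c_upper), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "concordance index (95% bootstrap CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Correlation heatmap with significance stars
#'
#' @param cm a `melbandsCorrelation`.
#' @return a ggplot object.
#' @export
plotCorrelationHeatmap <- function(cm) {
  dict <- factorDictionary()
  lab <- function(f) ifelse(is.na(dict[f]), f, dict[f])
  long <- expand.grid(a = rownames(cm$r), b = colnames(cm$r),
                      stringsAsFactors = FALSE)
  long$r <- as.numeric(cm$r)
  long$stars <- as.character(cm$stars)
  long$a <- factor(lab(long$a), levels = lab(rownames(cm$r)))
  long$b <- factor(lab(long$b), levels = rev(lab(colnames(cm$r))))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%s", .data$r, .data$stars)),
                       size = 2.6, na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
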