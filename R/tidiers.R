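#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a SparCC fit into a long pair table
#'
#' @param x A `sparcc_fit`.
#' @param ... Unused.
#' @return A tibble with `asv_a`, `asv_b`, `correlation` (unordered
#'   pairs).
#' @method tidy sparcc_fit
#' @export
tidy.sparcc_fit <- function(x, ...) {
  m <- x$correlations
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(asv_a = rownames(m)[idx[, 1]],
                 asv_b = colnames(m)[idx[, 2]],
                 correlation = m[idx])
}

#' @rdname tidy.sparcc_fit
#' @method glance sparcc_fit
#' @export
glance.sparcc_fit <- function(x, ...) {
  off <- x$correlations[upper.tri(x$correlations)]
  tibble::tibble(n_taxa = x$n_taxa, n_samples = x$n_samples,
                 n_resamples = x$config$n_resamples,
                 median_correlation = stats::median(off),
                 max_abs_correlation = max(abs(off)))
}

#' Tidy curve-clustering results
#'
#' @param x A `curve_clusters` object.
#' @param ... Unused.
#' @return The per-curve assignment tibble (`id`, `cluster`,
#'   `sil_width`).
#' @method tidy curve_clusters
#' @export
tidy.curve_clusters <- function(x, ...) x$assignments

#' @rdname tidy.curve_clusters
#' @method glance curve_clusters
#' @export
glance.curve_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n_curves = nrow(x$assignments),
                 avg_sil_width = max(x$silhouettes$avg_sil_width))
}

#' Plot a fitted distance-decay curve
#'
#' @param object A `decay_curve` from [distance_decay_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decay_curve
#' @export
autoplot.decay_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance_km, y = .data$fitted)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::labs(x = "Geographic distance (km)", y = "Dissimilarity (fitted)",
                  title = "Distance decay") +
    ggplot2::theme_minimal()
}

#' Plot clustered decay curves with cluster means
#'
#' @param object A `curve_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot curve_clusters
#' @export
autoplot.curve_clusters <- function(object, ...) {
  ggplot2::ggplot(object$mean_curves,
                  ggplot2::aes(x = .data$distance_km, y = .data$fitted,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = "Geographic distance (km)", y = "Mean z-scored dissimilarity",
                  colour = "Cluster", title = "Distance-decay curve clusters") +
    ggplot2::theme_minimal()
}

#' Plot mechanism fractions across temperature-difference bins
#'
#' @param object A `mechanism_fractions` tibble from
#'   [fractions_by_temperature_difference()].
#' @param ... Unused.
#' @return A stacked-area ggplot of label fractions over the temperature
#'   difference.
#' @method autoplot mechanism_fractions
#' @export
autoplot.mechanism_fractions <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$fraction))
  ggplot2::ggplot(dat, ggplot2::aes(x = (.data$dT_lower + .data$dT_upper) / 2,
                                    y = .data$fraction, fill = .data$label)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "Temperature difference (deg C)", y = "Fraction of pairs",
                  fill = "Mechanism") +
    ggplot2::theme_minimal()
}

#' Plot a Mantel correlogram
#'
#' @param object A `mantel_correlogram` tibble.
#' @param alpha Significance level for highlighting (default 0.05).
#' @param ... Unused.
#' @return A ggplot object; filled points are classes significant after
#'   progressive correction.
#' @method autoplot mantel_correlogram
#' @export
autoplot.mantel_correlogram <- function(object, alpha = 0.05, ...) {
  dat <- dplyr::mutate(tibble::as_tibble(object),
                       significant = !is.na(.data$p_corrected) &
                         .data$p_corrected <= alpha)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class_index, y = .data$mantel_r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white")) +
    ggplot2::labs(x = "Phylogenetic distance class", y = "Mantel r",
                  fill = paste0("p <= ", alpha)) +
    ggplot2::theme_minimal()
}
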