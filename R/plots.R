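# ggplot2 visualisations of the result objects.

#' @export
#' @method autoplot enrichment_curve
autoplot.enrichment_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$frac_screened,
                               y = .data$frac_actives)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Fraction of library screened",
                  y = "Fraction of actives recovered",
                  title = "Enrichment curve") +
    ggplot2::theme_minimal()
}

#' @export
plot.enrichment_curve <- function(x, ...) print(autoplot(x, ...))

#' @export
#' @method autoplot ee_clustering
autoplot.ee_clustering <- function(object, ...) {
  d <- tibble(
    ee = object$values,
    cluster = factor(ee_cluster_index(object$values, object))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ee, y = 0,
                                  colour = .data$cluster)) +
    ggplot2::geom_jitter(height = 0.3, width = 0, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$boundaries, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "Electrostatic energy (kcal/mol)", y = NULL,
                  colour = "Cluster",
                  title = "Electrostatic-energy clusters (0 = lowest)") +
    ggplot2::theme_minimal()
}

#' @export
plot.ee_clustering <- function(x, ...) print(autoplot(x, ...))

#' @export
#' @method autoplot enrichment_result
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(object$folds, ggplot2::aes(x = .data$frac_pass)) +
    ggplot2::geom_histogram(bins = 20, fill = "#2c7fb8", colour = "white") +
    ggplot2::geom_vline(xintercept = object$frac_reference_pass,
                        linetype = "dashed") +
    ggplot2::labs(x = "Reference pass rate per fold (%)", y = "Folds",
                  title = sprintf("Sub-sampled enrichment (EF = %.3g)",
                                  object$enrichment_factor)) +
    ggplot2::theme_minimal()
}

#' @export
plot.enrichment_result <- function(x, ...) print(autoplot(x, ...))

#' Distribution plots of the descriptor panel
#'
#' Faceted histograms of the descriptor columns of a molecule table, split
#' by class where a `label` column is present — the property-profile view
#' used to characterise known antagonists (charge, nitrogen count, logP,
#' molecular weight and friends).
#'
#' @param data A descriptor tibble.
#' @param descriptors Descriptor columns to plot; defaults to every panel
#'   descriptor present.
#' @return A ggplot object.
#' @export
plot_descriptor_distributions <- function(data, descriptors = NULL) {
  if (is.null(descriptors)) {
    descriptors <- intersect(descriptor_panel()$name, names(data))
  }
  check_columns(data, descriptors, "`data`")
  long <- tidyr::pivot_longer(
    data[, c(descriptors, intersect("label", names(data)))],
    dplyr::all_of(descriptors),
    names_to = "descriptor", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value))
  p <- if ("label" %in% names(long)) {
    p + ggplot2::geom_histogram(
      ggplot2::aes(fill = .data$label), bins = 30,
      position = "identity", alpha = 0.6)
  } else {
    p + ggplot2::geom_histogram(bins = 30, fill = "#2c7fb8")
  }
  p +
    ggplot2::facet_wrap(~descriptor, scales = "free") +
    ggplot2::labs(x = NULL, y = "Molecules") +
    ggplot2::theme_minimal()
}
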