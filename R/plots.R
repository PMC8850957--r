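#' Plot methods
#'
#' `autoplot()` methods for the package's result types: factor-1 loading
#' spectra for PLS calibrations, scree/loading views for PCA, per-ion
#' correlation profiles, and measured-vs-predicted scatter for validation
#' reports (via [plot_validation()]).
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name pymbms-plots
NULL

#' @rdname pymbms-plots
#' @export
autoplot.pls1_fit <- function(object, ...) {
  d <- factor1_loadings(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mz, y = .data$loading)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "m/z", y = "factor-1 loading",
                  title = "PLS1 factor-1 spectral loadings") +
    ggplot2::theme_minimal()
}

#' @rdname pymbms-plots
#' @export
autoplot.mbms_pca <- function(object, ...) {
  d <- tibble(
    component = seq_along(object$explained),
    explained = object$explained
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$explained)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = "principal component", y = "explained variance") +
    ggplot2::theme_minimal()
}

#' Per-ion correlation profile plot
#'
#' @param profile Output of [correlation_profile()].
#' @param highlight Optional integer m/z values to label.
#' @return A ggplot object.
#' @export
plot_correlation_profile <- function(profile, highlight = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$mz, y = .data$r)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "m/z", y = "Pearson r with trait") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    d <- profile[profile$mz %in% highlight, ]
    p <- p + ggplot2::geom_point(data = d, colour = "red") +
      ggplot2::geom_text(data = d, ggplot2::aes(label = .data$mz),
                         vjust = -0.6, size = 3)
  }
  p
}

#' Measured vs predicted scatter
#'
#' @param measured,predicted Aligned numeric vectors.
#' @param trait Axis label.
#' @return A ggplot object.
#' @export
plot_validation <- function(measured, predicted, trait = "trait") {
  d <- tibble(measured = measured, predicted = predicted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$measured, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = paste("measured", trait), y = paste("predicted", trait)) +
    ggplot2::theme_minimal()
}
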