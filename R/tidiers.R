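#' Tidy and glance methods
#'
#' broom-style summaries: `tidy()` returns per-term/per-channel tibbles,
#' `glance()` one-row model summaries.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name pymbms-tidiers
NULL

#' @rdname pymbms-tidiers
#' @export
tidy.pls1_fit <- function(x, ...) {
  tibble(
    mz = x$mz %||% seq_along(x$coef),
    coefficient = x$coef,
    weight_1 = x$weights[, 1],
    loading_1 = factor1_loadings(x)$loading
  )
}

#' @rdname pymbms-tidiers
#' @export
glance.pls1_fit <- function(x, ...) {
  rmse <- if (!is.null(x$fitted)) sqrt(mean((x$fitted - x$y)^2)) else NA_real_
  r2 <- if (!is.null(x$fitted) && sd(x$fitted) > 0) cor(x$y, x$fitted)^2 else NA_real_
  tibble(
    n = length(x$sample_ids),
    n_factors = x$n_factors,
    rmse_calibration = rmse,
    r2_calibration = r2,
    normalization = x$normalization
  )
}

#' @rdname pymbms-tidiers
#' @export
tidy.mbms_pca <- function(x, ...) {
  load <- x$loadings
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  bind_cols(tibble(mz = x$mz %||% seq_len(nrow(load))), as_tibble(load))
}

#' @rdname pymbms-tidiers
#' @export
glance.mbms_pca <- function(x, ...) {
  tibble(
    rank = x$rank,
    n_components = ncol(x$loadings),
    pc1_explained = x$explained[1],
    pc2_explained = if (length(x$explained) > 1) x$explained[2] else NA_real_
  )
}

#' @rdname pymbms-tidiers
#' @export
tidy.variance_decomposition <- function(x, ...) {
  tidyr::pivot_longer(
    as_tibble(x)[intersect(c("sigma2_G", "sigma2_E", "H2", "ci_low", "ci_high"),
                           names(x))],
    dplyr::everything(),
    names_to = "component", values_to = "estimate"
  )
}
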