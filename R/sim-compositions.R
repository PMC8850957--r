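#' Draw latent cell-wall compositions
#'
#' Samples (glucose, xylose, lignin) from a multivariate normal with the
#' configured means, SDs and correlations, rejection-resampled into the
#' configured sugar ranges (rejection preserves the correlation structure
#' better than clipping), plus an independent S/G draw. Deterministic given
#' the seed.
#'
#' @param n Number of samples (>= 2).
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A tibble of latent truth: `sample_id`, `glucose_dw_pct`,
#'   `xylose_dw_pct`, `lignin_pct`, `sg_ratio`.
#' @examples
#' sample_compositions(5, seed = 1)
#' @export
sample_compositions <- function(n, config = generator_config(), seed = 1) {
  stopifnot(n >= 2)
  mu <- c(config$glucose$mean, config$xylose$mean, config$lignin$mean)
  sds <- c(config$glucose$sd, config$xylose$sd, config$lignin$sd)
  Sigma <- diag(sds) %*% config$trait_cor %*% diag(sds)
  withr::with_seed(seed, {
    acc <- matrix(numeric(0), 0, 3)
    tried <- 0L
    while (nrow(acc) < n) {
      draw <- if (all(sds == 0)) {
        matrix(mu, n, 3, byrow = TRUE)
      } else {
        MASS::mvrnorm(max(n, 100), mu, Sigma)
      }
      tried <- tried + nrow(draw)
      keep <- draw[, 1] >= config$glucose$range[1] &
        draw[, 1] <= config$glucose$range[2] &
        draw[, 2] >= config$xylose$range[1] &
        draw[, 2] <= config$xylose$range[2] &
        draw[, 3] > 0 &
        rowSums(draw) < 100
      acc <- rbind(acc, draw[keep, , drop = FALSE])
      if (tried >= 100 * n && nrow(acc) < tried / 100) {
        abort("composition ranges accept < 1% of draws; config infeasible",
              class = "pymbms_error_infeasible_config")
      }
    }
    acc <- acc[seq_len(n), , drop = FALSE]
    sg <- rnorm(n, config$sg$mean, config$sg$sd)
    sg <- pmax(sg, 0.1)
    tibble(
      sample_id = sprintf("s%04d", seq_len(n)),
      glucose_dw_pct = acc[, 1],
      xylose_dw_pct = acc[, 2],
      lignin_pct = acc[, 3],
      sg_ratio = sg
    )
  })
}

#' Simulate reference (hydrolysis + NMR style) measurements
#'
#' Adds independent Gaussian measurement error with the configured
#' reference SD to the latent sugar contents, emulating the wet-chemistry
#' reference pipeline that calibrations are trained against.
#'
#' @param truth Output of [sample_compositions()].
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A tibble with `sample_id`, `glucose_dw_pct`, `xylose_dw_pct`
#'   (measured values, DW%).
#' @export
nmr_measure <- function(truth, config = generator_config(), seed = 1) {
  n <- nrow(truth)
  withr::with_seed(seed, tibble(
    sample_id = truth$sample_id,
    glucose_dw_pct = truth$glucose_dw_pct + rnorm(n, 0, config$reference_sd),
    xylose_dw_pct = truth$xylose_dw_pct + rnorm(n, 0, config$reference_sd)
  ))
}
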