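#' Principal component analysis of spectra
#'
#' Mean-centered PCA via singular value decomposition. Explained-variance
#' fractions are the normalized squared singular values (equivalently, the
#' eigenvalues of the sample covariance matrix); they are non-increasing and
#' sum to 1 over the full rank. Each loading vector's sign is fixed so its
#' largest-magnitude element is positive.
#'
#' @param x A replicate-averaged spectra table or numeric matrix.
#' @param n_components Number of components to retain (default: full rank).
#' @return An `mbms_pca` object with `loadings` (variables by components),
#'   `scores`, `explained` (variance fractions), and `mz` when fitted on
#'   spectra.
#' @examples
#' sim <- sample_compositions(30, seed = 1)
#' sp <- average_replicates(compose_spectra(sim, seed = 2))
#' fit_pca(sp)$explained[1:3]
#' @export
fit_pca <- function(x, n_components = NULL) {
  xm <- resolve_design(x)
  X <- xm$matrix
  if (nrow(X) < 2) abort("PCA needs at least 2 samples", class = "pymbms_error_config")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  ev <- sv$d^2
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  keep <- min(n_components %||% rank, rank)
  expl_all <- ev[seq_len(rank)] / sum(ev[seq_len(rank)])
  load <- sv$v[, seq_len(keep), drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, "*")
  scores <- sweep(sv$u[, seq_len(keep), drop = FALSE] %*%
                    diag(sv$d[seq_len(keep)], keep), 2, flip, "*")
  structure(
    list(
      loadings = load,
      scores = scores,
      explained = expl_all[seq_len(keep)],
      explained_full = expl_all,
      rank = rank,
      center = colMeans(X),
      mz = xm$mz,
      sample_ids = xm$sample_ids
    ),
    class = "mbms_pca"
  )
}

#' @export
print.mbms_pca <- function(x, ...) {
  cat("PCA: rank ", x$rank, ", ", ncol(x$loadings), " component(s) retained\n",
      "Explained variance: ",
      paste0(signif(100 * utils::head(x$explained, 5), 3), "%", collapse = ", "),
      if (length(x$explained) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Per-ion trait correlation profile
#'
#' Pearson correlation between each channel's intensities and a trait across
#' samples, the per-ion analogue of a calibration's loading plot. Channels
#' with zero variance get `r = 0` and `constant = TRUE` rather than `NA`.
#'
#' @param x A replicate-averaged spectra table or numeric matrix.
#' @param trait Numeric trait values aligned with rows of `x`.
#' @return A tibble with `mz` (or column index), `r`, and `constant`.
#' @export
correlation_profile <- function(x, trait) {
  xm <- resolve_design(x)
  X <- xm$matrix
  stopifnot(length(trait) == nrow(X))
  if (sd(trait) == 0) {
    abort("trait is constant", class = "pymbms_error_degenerate_response")
  }
  sds <- apply(X, 2, sd)
  r <- rep(0, ncol(X))
  ok <- sds > 0
  r[ok] <- drop(cor(X[, ok, drop = FALSE], trait))
  tibble(
    mz = xm$mz %||% seq_len(ncol(X)),
    r = r,
    constant = !ok
  )
}
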