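#' Fit a single-response partial least squares model (NIPALS)
#'
#' PLS1 by the NIPALS recursion on mean-centered data. Per factor `a`:
#' `w_a = X'y / ||X'y||` (unit-norm weight), `t_a = X w_a` (score),
#' `p_a = X't_a / (t_a't_a)` (x-loading), `q_a = y't_a / (t_a't_a)`
#' (y-loading), then deflation `X <- X - t_a p_a'`, `y <- y - t_a q_a`.
#' The composite coefficient vector `b = W (P'W)^{-1} q` gives predictions
#' `y_mean + (x - x_mean)' b`. X is mean-centered but not variance-scaled
#' (all channels share intensity units); pass `scale = TRUE` to opt in to
#' unit-variance scaling.
#'
#' Training score vectors are mutually orthogonal and each weight vector has
#' unit norm; both are asserted after fitting. When `n_factors` equals the
#' rank of the centered X, the coefficients coincide with the least-squares
#' solution.
#'
#' @param x A replicate-averaged spectra table or a numeric matrix
#'   (samples by variables).
#' @param y Numeric response, aligned with the rows of `x` (trait values,
#'   e.g. percent dry weight glucose).
#' @param n_factors Number of latent factors. Glucose calibrations
#'   conventionally use 4 and xylose 5.
#' @param scale Scale columns to unit variance before fitting.
#' @return A `pls1_fit` object: means, per-factor weights `W`, x-loadings
#'   `P`, y-loadings `q`, scores `scores`, coefficients `coef`, training
#'   sample ids and the training normalization state.
#' @examples
#' sim <- sample_compositions(40, seed = 1)
#' sp <- average_replicates(compose_spectra(sim, seed = 2))
#' fit <- fit_pls1(sp, sim$glucose_dw_pct, n_factors = 4)
#' glance(fit)
#' @export
fit_pls1 <- function(x, y, n_factors, scale = FALSE) {
  xm <- resolve_design(x)
  X <- xm$matrix
  stopifnot(is.numeric(y), length(y) == nrow(X))
  n_factors <- as.integer(n_factors)
  if (n_factors < 1) abort("n_factors must be >= 1", class = "pymbms_error_config")
  if (nrow(X) < n_factors + 2) {
    abort("need at least n_factors + 2 training samples",
          class = "pymbms_error_config")
  }
  if (sd(y) == 0) {
    abort("response has zero variance", class = "pymbms_error_degenerate_response")
  }
  x_mean <- colMeans(X)
  x_scale <- if (scale) {
    s <- apply(X, 2, sd)
    ifelse(s > 0, s, 1)
  } else {
    rep(1, ncol(X))
  }
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  y_mean <- mean(y)
  yc <- y - y_mean

  p <- ncol(X)
  W <- P <- matrix(0, p, n_factors)
  Tm <- matrix(0, nrow(X), n_factors)
  q <- numeric(n_factors)
  tol <- max(sum(Xc^2), .Machine$double.eps) * 1e-12
  for (a in seq_len(n_factors)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w^2))
    if (wn^2 <= tol) {
      abort(
        paste0("rank deficient: only ", a - 1L, " factor(s) extractable"),
        class = "pymbms_error_rank_deficient",
        achieved_factors = a - 1L
      )
    }
    w <- w / wn
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    if (tt <= tol) {
      abort(
        paste0("rank deficient: only ", a - 1L, " factor(s) extractable"),
        class = "pymbms_error_rank_deficient",
        achieved_factors = a - 1L
      )
    }
    p_ <- drop(crossprod(Xc, t_)) / tt
    q_ <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - t_ * q_
    W[, a] <- w; P[, a] <- p_; q[a] <- q_; Tm[, a] <- t_
  }
  b <- drop(W %*% solve(crossprod(P, W), q)) / x_scale

  fit <- structure(
    list(
      n_factors = n_factors,
      x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
      weights = W, x_loadings = P, y_loadings = q, scores = Tm,
      coef = b,
      mz = xm$mz,
      sample_ids = xm$sample_ids,
      normalization = xm$normalization,
      scaled = scale
    ),
    class = "pls1_fit"
  )
  assert_pls_invariants(fit)
  fit$fitted <- predict(fit, x)
  fit$y <- y
  fit
}

assert_pls_invariants <- function(fit) {
  wn <- sqrt(colSums(fit$weights^2))
  stopifnot(all(abs(wn - 1) < 1e-10))
  Tm <- fit$scores
  g <- crossprod(Tm)
  off <- abs(g - diag(diag(g), nrow(g)))
  stopifnot(max(off) <= 1e-8 * max(diag(g)))
  invisible(fit)
}

# Accept a spectra table or plain matrix as the design
resolve_design <- function(x) {
  if (inherits(x, "mbms_spectra")) {
    list(
      matrix = spectra_matrix(x),
      mz = mz_channels(),
      sample_ids = x$sample_id,
      normalization = normalization_state(x)
    )
  } else if (is.matrix(x) && is.numeric(x)) {
    list(matrix = x, mz = NULL,
         sample_ids = rownames(x) %||% as.character(seq_len(nrow(x))),
         normalization = NA_character_)
  } else {
    abort("x must be a spectra table or numeric matrix",
          class = "pymbms_error_config")
  }
}

#' Predict from a fitted PLS1 model
#'
#' Applies `y_mean + (x - x_mean)' b` row-wise. When both the model and the
#' new data carry a normalization state, a mismatch is an error. Predicting
#' the training-mean spectrum returns `y_mean` exactly.
#'
#' @param object A [fit_pls1()] model.
#' @param newdata A spectra table or numeric matrix with the training
#'   channel layout.
#' @param ... Unused.
#' @return Numeric vector of predicted trait values.
#' @export
predict.pls1_fit <- function(object, newdata, ...) {
  xm <- resolve_design(newdata)
  if (!is.na(object$normalization) && !is.na(xm$normalization) &&
      !identical(object$normalization, xm$normalization)) {
    abort(
      paste0("normalization mismatch: model trained on '", object$normalization,
             "', data are '", xm$normalization, "'"),
      class = "pymbms_error_inconsistent_normalization"
    )
  }
  X <- xm$matrix
  stopifnot(ncol(X) == length(object$x_mean))
  unname(drop(object$y_mean + sweep(X, 2, object$x_mean) %*% object$coef))
}

#' Cross-validate a PLS1 calibration
#'
#' Out-of-fold root-mean-square error (RMSECV) for each factor count from 1
#' to `max_factors`. The default scheme is leave-one-out for up to 150
#' samples, otherwise 10 random segments drawn with the given seed;
#' results are deterministic given the seed.
#'
#' @inheritParams fit_pls1
#' @param max_factors Largest factor count to evaluate.
#' @param scheme `"loo"`, `"kfold"`, or `"auto"` (the default rule above).
#' @param k Number of folds for `"kfold"`.
#' @param seed Integer seed for fold assignment.
#' @return A tibble with `n_factors`, `rmsecv`, and the number of refits in
#'   the `n_fits` attribute.
#' @export
cross_validate <- function(x, y, max_factors, scheme = c("auto", "loo", "kfold"),
                           k = 10, seed = 1, scale = FALSE) {
  scheme <- match.arg(scheme)
  xm <- resolve_design(x)
  X <- xm$matrix
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (scheme == "auto") scheme <- if (n <= 150) "loo" else "kfold"
  folds <- if (scheme == "loo") {
    seq_len(n)
  } else {
    if (k > n) abort("k exceeds the number of samples",
                     class = "pymbms_error_invalid_folds")
    withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  }
  preds <- matrix(NA_real_, n, max_factors)
  n_fits <- 0L
  for (f in unique(folds)) {
    hold <- folds == f
    fit <- fit_pls1(X[!hold, , drop = FALSE], y[!hold], max_factors,
                    scale = scale)
    n_fits <- n_fits + 1L
    for (a in seq_len(max_factors)) {
      sub <- truncate_factors(fit, a)
      preds[hold, a] <- predict(sub, X[hold, , drop = FALSE])
    }
  }
  out <- tibble(
    n_factors = seq_len(max_factors),
    rmsecv = vapply(seq_len(max_factors),
                    function(a) sqrt(mean((preds[, a] - y)^2)), 0)
  )
  attr(out, "n_fits") <- n_fits
  attr(out, "scheme") <- scheme
  out
}

# Reassemble coefficients from the first `a` factors of a fitted model
truncate_factors <- function(fit, a) {
  W <- fit$weights[, seq_len(a), drop = FALSE]
  P <- fit$x_loadings[, seq_len(a), drop = FALSE]
  q <- fit$y_loadings[seq_len(a)]
  fit$coef <- drop(W %*% solve(crossprod(P, W), q)) / fit$x_scale
  fit$n_factors <- a
  fit
}

#' Factor-1 spectral loadings
#'
#' The first-factor x-loading vector indexed by m/z, with the sign fixed so
#' that the factor-1 y-loading is positive: channels that load positively
#' are positively associated with the trait.
#'
#' @param fit A [fit_pls1()] model trained on spectra.
#' @return A tibble with `mz` and `loading`.
#' @export
factor1_loadings <- function(fit) {
  stopifnot(inherits(fit, "pls1_fit"))
  sgn <- if (fit$y_loadings[1] < 0) -1 else 1
  tibble(
    mz = fit$mz %||% seq_along(fit$x_mean),
    loading = sgn * fit$x_loadings[, 1]
  )
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat("PLS1 (NIPALS) calibration: ", x$n_factors, " factor(s), ",
      length(x$x_mean), " variables, ", length(x$sample_ids),
      " training samples\n", sep = "")
  if (!is.null(x$fitted)) {
    cat("Training RMSE: ", signif(sqrt(mean((x$fitted - x$y)^2)), 4), "\n",
        sep = "")
  }
  invisible(x)
}

#' Serialize a PLS model to JSON
#'
#' Stores means, factor matrices, coefficients and provenance (training
#' ids, normalization state, factor count) in a single JSON file;
#' `read_pls_model()` restores a model whose predictions match the original
#' to full precision.
#'
#' @param fit A [fit_pls1()] model.
#' @param path Output file.
#' @return `fit`, invisibly (`read_pls_model()` returns the model).
#' @export
write_pls_model <- function(fit, path) {
  stopifnot(inherits(fit, "pls1_fit"))
  payload <- fit[c("n_factors", "x_mean", "x_scale", "y_mean", "weights",
                   "x_loadings", "y_loadings", "coef", "mz", "sample_ids",
                   "normalization", "scaled")]
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(fit)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("weights", "x_loadings")) p[[nm]] <- as.matrix(p[[nm]])
  p$normalization <- p$normalization %||% NA_character_
  structure(p, class = "pls1_fit")
}
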