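#' Broad-sense heritability from clonally replicated records
#'
#' Treats genotype as a random group effect in a one-way random-effects
#' model and returns the variance decomposition and broad-sense
#' heritability `H2 = sigma2_G / (sigma2_G + sigma2_E)`. Clonal replication
#' (multiple ramets per genotype) identifies total genotypic variance
#' directly, which is what broad-sense heritability measures.
#'
#' `method = "moments"` uses the one-way ANOVA expectations with the
#' unbalanced-design coefficient `n0 = (N - sum(n_i^2)/N) / (k - 1)`:
#' `sigma2_G = (MS_between - MS_within) / n0` truncated at zero, and
#' `sigma2_E = MS_within`. `method = "reml"` maximizes the restricted
#' likelihood of the same model via `lme4::lmer`. H2 always lies in
#' `[0, 1]`.
#'
#' @param records Tibble with a genotype column and a phenotype column; one
#'   row per ramet.
#' @param value Name of the phenotype column.
#' @param genotype Name of the genotype column.
#' @param method `"moments"` or `"reml"`.
#' @return A one-row `variance_decomposition` tibble: `sigma2_G`,
#'   `sigma2_E`, `H2`, `n_genotypes`, `n_records`, `method`.
#' @examples
#' d <- tibble::tibble(genotype_id = rep(c("a", "b", "c"), each = 2),
#'                     value = c(1, 1, 2, 2, 3, 3))
#' estimate_H2(d)
#' @export
estimate_H2 <- function(records, value = "value", genotype = "genotype_id",
                        method = c("moments", "reml")) {
  method <- match.arg(method)
  stopifnot(all(c(value, genotype) %in% names(records)))
  y <- records[[value]]
  g <- factor(records[[genotype]])
  ni <- tabulate(g)
  k <- nlevels(g)
  N <- length(y)
  if (k < 2 || max(ni) < 2) {
    abort("need >= 2 genotypes and clonal replication (some n_i >= 2)",
          class = "pymbms_error_non_estimable")
  }
  if (all(ni == 1)) {
    abort("no clonal replication: residual variance is not identifiable",
          class = "pymbms_error_non_estimable")
  }
  if (method == "moments") {
    gm <- tapply(y, g, mean)
    grand <- mean(y)
    ss_between <- sum(ni * (gm - grand)^2)
    ss_within <- sum((y - gm[g])^2)
    ms_between <- ss_between / (k - 1)
    ms_within <- ss_within / (N - k)
    n0 <- (N - sum(ni^2) / N) / (k - 1)
    s2g <- max(0, (ms_between - ms_within) / n0)
    s2e <- ms_within
  } else {
    fit <- lme4::lmer(y ~ 1 + (1 | g), data = data.frame(y = y, g = g),
                      REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2g <- vc$vcov[vc$grp == "g"]
    s2e <- vc$vcov[vc$grp == "Residual"]
  }
  h2 <- if (s2g + s2e == 0) 0 else s2g / (s2g + s2e)
  out <- tibble(
    sigma2_G = s2g, sigma2_E = s2e, H2 = h2,
    n_genotypes = k, n_records = N, method = method
  )
  class(out) <- c("variance_decomposition", class(out))
  out
}

#' Bootstrap confidence interval for heritability
#'
#' Percentile interval from resampling genotypes (whole clonal groups) with
#' replacement; deterministic given the seed.
#'
#' @inheritParams estimate_H2
#' @param n_boot Number of bootstrap resamples (>= 200 recommended).
#' @param seed Integer seed.
#' @param level Interval coverage.
#' @return A [estimate_H2()] row with `ci_low` and `ci_high` columns added.
#' @export
bootstrap_ci <- function(records, value = "value", genotype = "genotype_id",
                         method = c("moments", "reml"), n_boot = 500,
                         seed = 1, level = 0.95) {
  method <- match.arg(method)
  est <- estimate_H2(records, value, genotype, method)
  g <- records[[genotype]]
  gl <- unique(g)
  if (length(gl) < 10) {
    warn("fewer than 10 genotypes: bootstrap CI is unreliable")
  }
  idx_by_g <- split(seq_along(g), g)[as.character(gl)]
  h2s <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample(length(gl), replace = TRUE)
      rows <- unlist(idx_by_g[pick], use.names = FALSE)
      # relabel so resampled copies of one genotype stay distinct groups
      reps <- rep(seq_along(pick), lengths(idx_by_g[pick]))
      d <- records[rows, , drop = FALSE]
      d[[genotype]] <- reps
      estimate_H2(d, value, genotype, method)$H2
    }, 0)
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(h2s, c(alpha, 1 - alpha), type = 7))
  est$ci_low <- ci[1]
  est$ci_high <- ci[2]
  est
}

#' Trait prediction, spatial correction and heritability in one pass
#'
#' The pedigree workflow: predict a trait for every ramet from its spectrum
#' (PLS model or single-point standard), remove the field microspatial
#' trend with [tps_correct()], and estimate broad-sense heritability from
#' the clonally replicated records. Optionally computes per-ion
#' heritability for a list of channels (each channel's corrected intensity
#' treated as a phenotype).
#'
#' @param spectra A normalized spectra table (one row per ramet replicate;
#'   replicates are averaged internally per `sample_id`).
#' @param metadata Sample metadata with `sample_id`, `genotype_id`,
#'   `field_row`, `field_col`.
#' @param trait_model A [fit_pls1()] model, a [reference_standard()], or a
#'   named list of them (one result row per entry). May also be `NULL` to
#'   skip trait prediction when `ions` are given.
#' @param ions Optional integer vector of m/z channels for per-ion
#'   heritability.
#' @param tps Apply thin-plate-spline correction before estimating H2.
#' @param method Variance-component method, `"moments"` or `"reml"`.
#' @param knots Spline basis dimension passed to [tps_correct()].
#' @return A tibble with one row per trait/ion: the [estimate_H2()] columns
#'   plus `trait`.
#' @export
heritability_pipeline <- function(spectra, metadata, trait_model = NULL,
                                  ions = NULL, tps = TRUE,
                                  method = c("moments", "reml"), knots = 60) {
  method <- match.arg(method)
  stopifnot(all(c("sample_id", "genotype_id", "field_row", "field_col")
                %in% names(metadata)))
  avg <- if (anyDuplicated(spectra$sample_id) > 0) {
    average_replicates(spectra)
  } else {
    spectra
  }
  models <- if (is.null(trait_model)) {
    list()
  } else if (inherits(trait_model, c("pls1_fit", "reference_standard"))) {
    nm <- if (inherits(trait_model, "reference_standard")) trait_model$target else "trait"
    setNames(list(trait_model), nm)
  } else {
    trait_model
  }
  one_trait <- function(nm, vals) {
    d <- tibble(sample_id = avg$sample_id, value = vals) |>
      dplyr::inner_join(metadata, by = "sample_id")
    if (tps) d <- tps_correct(d, knots = knots)
    est <- estimate_H2(d, method = method)
    est$trait <- nm
    est
  }
  rows <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    vals <- if (inherits(m, "pls1_fit")) {
      predict(m, avg)
    } else {
      single_point_estimate(avg, m, col = ".est")$.est
    }
    rows[[length(rows) + 1L]] <- one_trait(nm, vals)
  }
  X <- as.matrix(avg[mz_cols()])
  for (mz in ions) {
    rows[[length(rows) + 1L]] <-
      one_trait(paste0("mz_", mz), X[, paste0("mz_", mz)])
  }
  dplyr::bind_rows(rows)
}
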