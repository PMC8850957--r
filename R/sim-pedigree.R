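#' Simulate a clonally replicated factorial pedigree field trial
#'
#' Builds the full mating design (every mother x father family with
#' `n_progeny` genotypes), assigns each genotype a latent genotypic value
#' `g = GCA_mother + GCA_father + SCA + segregation deviation` on the
#' standardized trait scale, plants `n_ramets` clonal copies at random
#' distinct positions of the field grid, overlays a smooth spatial surface
#' (random low-frequency Fourier field rescaled to the configured
#' amplitude), and adds iid residual noise:
#' `phenotype = g + f(row, col) + e`.
#'
#' The realized broad-sense heritability implied by the latent values,
#' `sigma2_G / (sigma2_G + sigma2_E)`, is recorded in the `true_H2`
#' attribute along with the realized variance of the drawn genotype values.
#'
#' When `gconfig` is supplied, composition traits are shifted by the scaled
#' genotype values around the generator means and spectra are composed per
#' ramet, giving a full spectra + metadata + truth bundle.
#'
#' @param pconfig A [pedigree_sim_config()].
#' @param gconfig Optional [generator_config()]; when given, per-ramet
#'   compositions and spectra are generated.
#' @param seed Integer seed.
#' @param spectra Compose per-ramet spectra (requires `gconfig`; slower).
#' @return A list with `records` (one row per ramet: `sample_id`,
#'   `genotype_id`, `mother_id`, `father_id`, `field_row`, `field_col`,
#'   `value`, `genotype_value`, `spatial_effect`), `metadata` (per-ramet
#'   sample metadata), `truth` (per-genotype latent values), optionally
#'   `spectra` and `reference`, plus `true_H2`.
#' @export
simulate_pedigree <- function(pconfig = pedigree_sim_config(), gconfig = NULL,
                              seed = 1, spectra = !is.null(gconfig)) {
  if (spectra && is.null(gconfig)) gconfig <- generator_config()
  p <- pconfig
  n_geno <- p$n_mothers * p$n_fathers * p$n_progeny
  n <- n_geno * p$n_ramets
  out <- withr::with_seed(seed, {
    fam <- expand.grid(mother = seq_len(p$n_mothers),
                       father = seq_len(p$n_fathers))
    s2g <- p$sigma2_G
    gca_m <- rnorm(p$n_mothers, 0, sqrt(p$gca_m_frac * s2g))
    gca_f <- rnorm(p$n_fathers, 0, sqrt(p$gca_f_frac * s2g))
    sca <- matrix(rnorm(nrow(fam), 0, sqrt(p$sca_frac * s2g)),
                  p$n_mothers, p$n_fathers)
    seg_frac <- 1 - p$gca_m_frac - p$gca_f_frac - p$sca_frac
    fam_idx <- rep(seq_len(nrow(fam)), each = p$n_progeny)
    dev <- rnorm(n_geno, 0, sqrt(seg_frac * s2g))
    m_i <- fam$mother[fam_idx]
    f_i <- fam$father[fam_idx]
    g <- gca_m[m_i] + gca_f[f_i] + sca[cbind(m_i, f_i)] + dev
    truth <- tibble(
      genotype_id = sprintf("g%04d", seq_len(n_geno)),
      mother_id = sprintf("m%02d", m_i),
      father_id = sprintf("f%02d", f_i),
      genotype_value = g
    )

    grid <- expand.grid(field_row = seq_len(p$grid_rows),
                        field_col = seq_len(p$grid_cols))
    pos <- grid[sample(nrow(grid), n), ]
    surf <- if (p$spatial_amplitude > 0) {
      smooth_surface(pos$field_row, pos$field_col,
                     p$spatial_amplitude, p$spatial_length_scale)
    } else {
      numeric(n)
    }
    gi <- rep(seq_len(n_geno), each = p$n_ramets)
    e <- rnorm(n, 0, sqrt(p$sigma2_E))
    records <- tibble(
      sample_id = sprintf("%s_t%02d", truth$genotype_id[gi],
                          rep(seq_len(p$n_ramets), times = n_geno)),
      genotype_id = truth$genotype_id[gi],
      mother_id = truth$mother_id[gi],
      father_id = truth$father_id[gi],
      field_row = pos$field_row,
      field_col = pos$field_col,
      genotype_value = g[gi],
      spatial_effect = surf,
      value = g[gi] + surf + e
    )
    list(records = records, truth = truth)
  })
  out$config <- p
  out$true_H2 <- p$true_H2
  out$metadata <- tibble(
    sample_id = out$records$sample_id,
    genotype_id = out$records$genotype_id,
    population = "pedigree",
    mother_id = out$records$mother_id,
    father_id = out$records$father_id,
    field_row = out$records$field_row,
    field_col = out$records$field_col
  )
  if (spectra) {
    # map standardized phenotypes onto the composition trait and compose
    trait_col <- if (p$trait == "glucose") "glucose_dw_pct" else "xylose_dw_pct"
    comp <- sample_compositions(n, gconfig, seed = seed + 1L)
    comp$sample_id <- out$records$sample_id
    shift <- out$records$value * p$trait_scale_dw
    comp[[trait_col]] <- pmin(
      pmax(mean(comp[[trait_col]]) + shift,
           0.5 * mean(comp[[trait_col]])),
      95 - comp$lignin_pct - if (p$trait == "glucose") comp$xylose_dw_pct else comp$glucose_dw_pct
    )
    out$composition <- comp
    out$spectra <- compose_spectra(comp, gconfig, seed = seed + 2L)
    out$reference <- nmr_measure(comp, gconfig, seed = seed + 3L)
  }
  out
}

# Random smooth surface: sum of low-frequency cosine features, centered and
# rescaled to the requested SD over the sampled positions.
smooth_surface <- function(row, col, amplitude, length_scale, n_features = 8) {
  xy <- cbind(row, col)
  w <- matrix(rnorm(2 * n_features, 0, 1 / length_scale), 2, n_features)
  ph <- runif(n_features, 0, 2 * pi)
  a <- rnorm(n_features)
  f <- drop(cos(xy %*% w + matrix(ph, nrow(xy), n_features, byrow = TRUE)) %*% a)
  if (sd(f) == 0) return(numeric(length(f)))
  amplitude * (f - mean(f)) / sd(f)
}
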