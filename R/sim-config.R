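#' Synthetic composition and spectrum generator configuration
#'
#' Defaults emulate the statistical structure of a Populus trichocarpa
#' natural-variant population: glucose mean 48 DW% over 43-57, xylose mean
#' 17 DW% over 11-20, lignin mean 24.6 DW% (SD 1.0), S/G mean 2.1 (SD 0.1),
#' trait correlations r(glucose, xylose) = -0.76, r(xylose, lignin) =
#' +0.48, r(glucose, lignin) = -0.61, reference-measurement (hydrolysis +
#' NMR) error 1.0 DW% (0.01 mg/mg), and duplicate pyrolysis runs with 5%
#' per-channel multiplicative lognormal noise.
#'
#' Spectra are linear mixtures: each component's basis spectrum places 80%
#' of its mass on its annotated diagnostic ions and 20% on a shared
#' low-mass background profile (m/z 30-56), and the non-glucose/xylose/
#' lignin remainder of dry weight contributes background only, so total
#' pyrolyzate mass per sample is constant and TIC normalization is exact.
#' The S-/G-lignin split is solved per sample so that, at zero noise, the
#' S/G ion-ratio of the composed spectrum equals the sample's latent S/G
#' value; the operational definition of the ratio and the generator's
#' definition coincide.
#'
#' A user-supplied correlation matrix that is not positive semi-definite is
#' repaired by eigenvalue clipping, with a warning.
#'
#' @param glucose,xylose,lignin,sg Per-trait lists with `mean`, `sd`, and
#'   (for the sugars) `range`.
#' @param trait_cor 3x3 correlation matrix for (glucose, xylose, lignin).
#' @param spectral_noise_sd SD of per-channel lognormal noise.
#' @param n_replicates Pyrolysis replicates per sample.
#' @param reference_sd Reference-measurement SD, DW% (1.0 = 0.01 mg/mg).
#' @param basis Named list of basis-weight vectors (advanced; see
#'   [component_basis()]).
#' @return A `generator_config` list.
#' @export
generator_config <- function(glucose = list(mean = 48, sd = 2.5, range = c(43, 57)),
                             xylose = list(mean = 17, sd = 1.8, range = c(11, 20)),
                             lignin = list(mean = 24.6, sd = 1.0),
                             sg = list(mean = 2.1, sd = 0.1),
                             trait_cor = default_trait_cor(),
                             spectral_noise_sd = 0.05,
                             n_replicates = 2,
                             reference_sd = 1.0,
                             basis = default_basis_weights()) {
  stopifnot(
    glucose$range[1] <= glucose$mean, glucose$mean <= glucose$range[2],
    xylose$range[1] <= xylose$mean, xylose$mean <= xylose$range[2],
    spectral_noise_sd >= 0, reference_sd >= 0, n_replicates >= 1
  )
  trait_cor <- repair_correlation(trait_cor)
  structure(
    list(glucose = glucose, xylose = xylose, lignin = lignin, sg = sg,
         trait_cor = trait_cor, spectral_noise_sd = spectral_noise_sd,
         n_replicates = as.integer(n_replicates),
         reference_sd = reference_sd, basis = basis),
    class = "generator_config"
  )
}

default_trait_cor <- function() {
  matrix(c(1, -0.76, -0.61,
           -0.76, 1, 0.48,
           -0.61, 0.48, 1), 3, 3,
         dimnames = rep(list(c("glucose", "xylose", "lignin")), 2))
}

repair_correlation <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-8) {
    abort("correlation matrix must be symmetric", class = "pymbms_error_config")
  }
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-10) {
    warn("correlation matrix not positive semi-definite; repaired by eigenvalue clipping")
    v <- pmax(e$values, 1e-8)
    R2 <- e$vectors %*% diag(v) %*% t(e$vectors)
    d <- sqrt(diag(R2))
    R2 <- R2 / tcrossprod(d)
    dimnames(R2) <- dimnames(R)
    return(R2)
  }
  R
}

# Diagnostic-ion mass allocations of the four component basis spectra.
# Glucose pyrolyzate mass leans on m/z 69/70/84 (outside the reduced C6
# set), xylose on its lactone/anhydride channels 103/114; the S and G
# lignin allocations cover the standard monolignol marker ions.
default_basis_weights <- function() {
  list(
    glucose = c(`69` = 0.20, `70` = 0.17, `84` = 0.15, `126` = 0.13,
                `98` = 0.11, `57` = 0.10, `60` = 0.06, `73` = 0.05,
                `96` = 0.02, `144` = 0.01),
    xylose = c(`103` = 0.45, `114` = 0.20, `150` = 0.03, `57` = 0.09,
               `73` = 0.08, `85` = 0.08, `96` = 0.07),
    s_lignin = c(`154` = 0.18, `167` = 0.14, `168` = 0.13, `182` = 0.12,
                 `194` = 0.12, `208` = 0.11, `210` = 0.10, `152` = 0.05,
                 `180` = 0.05),
    g_lignin = c(`124` = 0.20, `137` = 0.17, `138` = 0.16, `150` = 0.14,
                 `164` = 0.14, `178` = 0.12, `120` = 0.07)
  )
}

#' Pedigree field-trial simulation configuration
#'
#' Defaults emulate a 7 x 7 factorial cross pedigree: 49 full-sib families,
#' 10 progeny per family (490 genotypes), 5 clonal ramets per genotype on a
#' 50 x 50 field grid with a smooth spatial surface of amplitude 0.3 (SD on
#' the standardized trait scale). Total phenotypic variance is 1.0 before
#' the spatial surface: the glucose trait splits it as sigma2_G = 0.32 /
#' sigma2_E = 0.68, the xylose trait as 0.34 / 0.66. Genotypic variance
#' divides into maternal GCA, paternal GCA, SCA and within-family
#' segregation as 0.2/0.2/0.1/0.5 of sigma2_G.
#'
#' @param trait `"glucose"` or `"xylose"` (sets the variance split), or use
#'   `sigma2_G`/`sigma2_E` directly.
#' @param n_mothers,n_fathers Parents per side of the factorial.
#' @param n_progeny Progeny genotypes per family.
#' @param n_ramets Clonal copies per genotype.
#' @param sigma2_G,sigma2_E Genotypic and residual variance on the
#'   standardized trait scale.
#' @param gca_m_frac,gca_f_frac,sca_frac Fractions of `sigma2_G` assigned
#'   to maternal GCA, paternal GCA and SCA; the remainder is within-family
#'   segregation.
#' @param grid_rows,grid_cols Field grid dimensions.
#' @param spatial_amplitude SD of the smooth spatial surface (0 disables).
#' @param spatial_length_scale Correlation length of the surface, in grid
#'   units.
#' @param trait_scale_dw SD multiplier mapping the standardized genotype
#'   value onto the composition trait, DW%.
#' @return A `pedigree_sim_config` list.
#' @export
pedigree_sim_config <- function(trait = c("glucose", "xylose"),
                                n_mothers = 7, n_fathers = 7,
                                n_progeny = 10, n_ramets = 5,
                                sigma2_G = NULL, sigma2_E = NULL,
                                gca_m_frac = 0.2, gca_f_frac = 0.2,
                                sca_frac = 0.1,
                                grid_rows = 50, grid_cols = 50,
                                spatial_amplitude = 0.3,
                                spatial_length_scale = 15,
                                trait_scale_dw = NULL) {
  trait <- match.arg(trait)
  if (is.null(sigma2_G)) sigma2_G <- if (trait == "glucose") 0.32 else 0.34
  if (is.null(sigma2_E)) sigma2_E <- 1 - sigma2_G
  stopifnot(sigma2_G >= 0, sigma2_E >= 0,
            gca_m_frac >= 0, gca_f_frac >= 0, sca_frac >= 0,
            gca_m_frac + gca_f_frac + sca_frac <= 1)
  n_geno <- n_mothers * n_fathers * n_progeny
  if (n_geno * n_ramets > grid_rows * grid_cols) {
    abort("field grid too small for the requested ramet count",
          class = "pymbms_error_layout_infeasible")
  }
  if (is.null(trait_scale_dw)) {
    trait_scale_dw <- if (trait == "glucose") 2.5 else 1.8
  }
  structure(
    list(trait = trait, n_mothers = n_mothers, n_fathers = n_fathers,
         n_progeny = n_progeny, n_ramets = n_ramets,
         sigma2_G = sigma2_G, sigma2_E = sigma2_E,
         gca_m_frac = gca_m_frac, gca_f_frac = gca_f_frac,
         sca_frac = sca_frac,
         grid_rows = grid_rows, grid_cols = grid_cols,
         spatial_amplitude = spatial_amplitude,
         spatial_length_scale = spatial_length_scale,
         trait_scale_dw = trait_scale_dw,
         true_H2 = sigma2_G / (sigma2_G + sigma2_E)),
    class = "pedigree_sim_config"
  )
}

config_hash <- function(config) {
  # cheap stable fingerprint for provenance sidecars (no digest dependency)
  s <- jsonlite::toJSON(unclass(config), digits = 15, auto_unbox = TRUE,
                        force = TRUE)
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 251 + 1)) %% 4294967291)
}
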