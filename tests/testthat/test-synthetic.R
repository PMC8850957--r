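test_that("composition draws honour the configured correlations and ranges", {
  truth <- sample_compositions(2000, seed = 71)
  r_gx <- cor(truth$glucose_dw_pct, truth$xylose_dw_pct)
  expect_lt(abs(r_gx - (-0.76)), 0.05)
  expect_true(all(truth$glucose_dw_pct >= 43 & truth$glucose_dw_pct <= 57))
  expect_true(all(truth$xylose_dw_pct >= 11 & truth$xylose_dw_pct <= 20))
  expect_true(all(truth$glucose_dw_pct + truth$xylose_dw_pct +
                    truth$lignin_pct < 100))
})

test_that("zero-SD configs collapse to the means and seeds reproduce exactly", {
  cfg <- generator_config(
    glucose = list(mean = 48, sd = 0, range = c(43, 57)),
    xylose = list(mean = 17, sd = 0, range = c(11, 20)),
    lignin = list(mean = 24.6, sd = 0),
    sg = list(mean = 2.1, sd = 0)
  )
  truth <- sample_compositions(5, cfg, seed = 1)
  expect_equal(truth$glucose_dw_pct, rep(48, 5))
  expect_equal(truth$sg_ratio, rep(2.1, 5))

  a <- sample_compositions(50, seed = 72)
  b <- sample_compositions(50, seed = 72)
  expect_identical(a, b)
})

test_that("an infeasible range/SD combination is refused", {
  cfg <- generator_config(
    glucose = list(mean = 50, sd = 40, range = c(49.99, 50.01)),
    xylose = list(mean = 17, sd = 30, range = c(16.99, 17.01))
  )
  expect_error(sample_compositions(100, cfg, seed = 1),
               class = "pymbms_error_infeasible_config")
})

test_that("a broken correlation matrix is repaired with a warning", {
  bad <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3, 3)
  expect_warning(cfg <- generator_config(trait_cor = bad), "clipping")
  ev <- eigen(cfg$trait_cor, symmetric = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_equal(diag(cfg$trait_cor), rep(1, 3), tolerance = 1e-8)
})

test_that("a pure-glucose composition at zero noise is proportional to the C6 basis", {
  truth <- tibble::tibble(sample_id = "s1", glucose_dw_pct = 100,
                          xylose_dw_pct = 0, lignin_pct = 0, sg_ratio = 2)
  sp <- compose_spectra(truth, n_replicates = 1, noise_sd = 0)
  v <- spectra_matrix(sp)[1, ]
  b <- component_basis()[, "glucose"]
  expect_equal(unname(v), b / sum(b), tolerance = 1e-12)
})

test_that("noiseless mixtures are linear and depend only on component ratios", {
  # 50/50 glucose-xylose sample equals the equal-weight basis combination
  half <- tibble::tibble(sample_id = "s1", glucose_dw_pct = 50,
                         xylose_dw_pct = 50, lignin_pct = 0, sg_ratio = 2)
  v <- spectra_matrix(compose_spectra(half, n_replicates = 1, noise_sd = 0))[1, ]
  b <- component_basis()
  expect_equal(unname(v), unname((b[, "glucose"] + b[, "xylose"]) / 2),
               tolerance = 1e-12)

  # doubling every component leaves component-specific channel ratios fixed
  base <- tibble::tibble(sample_id = "s1", glucose_dw_pct = 24,
                         xylose_dw_pct = 8, lignin_pct = 12, sg_ratio = 2)
  double <- dplyr::mutate(base, glucose_dw_pct = 48, xylose_dw_pct = 16,
                          lignin_pct = 24)
  a <- spectra_matrix(compose_spectra(base, n_replicates = 1, noise_sd = 0))[1, ]
  d <- spectra_matrix(compose_spectra(double, n_replicates = 1, noise_sd = 0))[1, ]
  # m/z 126 is glucose-only, 114 xylose-only, 154 S-lignin-only
  expect_equal(a[["mz_126"]] / a[["mz_114"]], d[["mz_126"]] / d[["mz_114"]],
               tolerance = 1e-10)
  expect_equal(a[["mz_154"]] / a[["mz_126"]], d[["mz_154"]] / d[["mz_126"]],
               tolerance = 1e-10)
})

test_that("noiseless spectra reproduce the latent S/G ratio exactly", {
  truth <- sample_compositions(20, seed = 74)
  sp <- compose_spectra(truth, n_replicates = 1, noise_sd = 0)
  expect_equal(sg_ratio(sp)$sg_ratio, truth$sg_ratio, tolerance = 1e-10)
})

test_that("composed spectra are valid: non-negative, unit TIC, deterministic", {
  truth <- sample_compositions(10, seed = 75)
  sp <- compose_spectra(truth, seed = 76)
  m <- as.matrix(sp[paste0("mz_", 30:450)])
  expect_true(all(m >= 0))
  expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-10)
  expect_equal(nrow(sp), 20)  # duplicate pyrolysis runs
  sp2 <- compose_spectra(truth, seed = 76)
  expect_identical(as.data.frame(sp), as.data.frame(sp2))
})

test_that("reference measurement error matches its configured SD", {
  truth <- sample_compositions(2000, seed = 77)
  ref <- nmr_measure(truth, seed = 78)
  rmse <- sqrt(mean((ref$glucose_dw_pct - truth$glucose_dw_pct)^2))
  expect_lt(abs(rmse - 1.0), 0.1)

  cfg0 <- generator_config(reference_sd = 0)
  exact <- nmr_measure(truth[1:5, ], cfg0, seed = 79)
  expect_equal(exact$glucose_dw_pct, truth$glucose_dw_pct[1:5])

  again <- nmr_measure(truth, seed = 78)
  expect_identical(ref, again)
})

test_that("pedigree bookkeeping: families, genotypes and ramets are exact", {
  sim <- simulate_pedigree(seed = 80)
  rec <- sim$records
  expect_equal(nrow(sim$truth), 490)
  expect_equal(nrow(rec), 2450)
  fams <- unique(paste(sim$truth$mother_id, sim$truth$father_id))
  expect_equal(length(fams), 49)
  expect_true(all(table(rec$genotype_id) == 5))
  expect_false(any(duplicated(rec[c("field_row", "field_col")])))
})

test_that("a null pedigree (no genotypic variance) gives F near 1", {
  pcfg <- pedigree_sim_config(sigma2_G = 0, sigma2_E = 1,
                              spatial_amplitude = 0)
  fs <- vapply(1:20, function(s) {
    rec <- simulate_pedigree(pcfg, seed = s)$records
    a <- anova(aov(value ~ genotype_id, data = rec))
    a$`F value`[1]
  }, 0)
  expect_lt(abs(mean(fs) - 1), 0.1)
})

test_that("realized latent heritability matches the configured value at large size", {
  pcfg <- pedigree_sim_config(n_mothers = 20, n_fathers = 20, n_progeny = 1,
                              n_ramets = 10, grid_rows = 64, grid_cols = 63,
                              spatial_amplitude = 0)
  h2 <- vapply(1:8, function(s) {
    sim <- simulate_pedigree(pcfg, seed = s + 500)
    rec <- sim$records
    vg <- var(sim$truth$genotype_value)
    ve <- mean(tapply(rec$value - rec$genotype_value, rec$genotype_id, var))
    vg / (vg + ve)
  }, 0)
  expect_lt(abs(mean(h2) - pcfg$true_H2), 0.03)
})

test_that("datasets round-trip through files byte-identically under one seed", {
  withr::with_tempdir({
    generate_dataset("natural", "d1", n = 30, seed = 81)
    generate_dataset("natural", "d2", n = 30, seed = 81)
    for (f in c("spectra.csv", "metadata.csv", "reference.csv", "truth.csv")) {
      expect_identical(readLines(file.path("d1", f)),
                       readLines(file.path("d2", f)))
    }
    sp <- read_spectra(file.path("d1", "spectra.csv"), normalization = "tic")
    expect_equal(nrow(sp), 60)  # 30 samples x 2 replicates

    expect_error(generate_dataset("natural", "d1", n = 30, seed = 81),
                 class = "pymbms_error_config")

    generate_dataset("pedigree", "d3",
                     pconfig = pedigree_sim_config(n_progeny = 2, n_ramets = 2,
                                                   grid_rows = 20, grid_cols = 20),
                     seed = 82)
    md <- read_sample_metadata(file.path("d3", "metadata.csv"))
    expect_true(all(md$population == "pedigree"))
    expect_false(anyNA(md$mother_id))
    prov <- jsonlite::read_json(file.path("d3", "provenance.json"))
    expect_equal(prov$seed, 82)
    expect_true(nzchar(prov$config_hash))
  })
})
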