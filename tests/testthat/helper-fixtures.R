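# Shared fixtures: all built in code, deterministic given their seeds.

# a tiny spectra table with given named channel intensities per row
toy_spectra <- function(rows, normalization = "raw") {
  tabs <- lapply(seq_along(rows), function(i) {
    toy_spectrum(rows[[i]],
                 sample_id = names(rows)[i] %||% paste0("s", i),
                 replicate_id = paste0("r", i))
  })
  sp <- as_spectra(dplyr::bind_rows(tabs))
  attr(sp, "normalization") <- normalization
  sp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mz_cols_test <- function() paste0("mz_", 30:450)

# natural-variant set: latent truth, replicate-averaged TIC spectra, and
# noisy reference measurements
sim_natural_set <- function(n, seed, config = generator_config()) {
  truth <- sample_compositions(n, config, seed = seed)
  spectra <- compose_spectra(truth, config, seed = seed + 1L)
  list(
    truth = truth,
    avg = average_replicates(spectra),
    ref = nmr_measure(truth, config, seed = seed + 2L)
  )
}

# one pedigree H2 recovery trial: simulate, optionally TPS-correct, estimate
h2_trial <- function(seed, pconfig = pedigree_sim_config(), tps = TRUE) {
  sim <- simulate_pedigree(pconfig, seed = seed, spectra = FALSE)
  rec <- sim$records
  if (tps) rec <- tps_correct(rec)
  estimate_H2(rec)$H2
}
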