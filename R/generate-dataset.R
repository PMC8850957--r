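#' Write a complete synthetic dataset to disk
#'
#' Generates a natural-variant or pedigree dataset and writes four CSVs plus
#' a JSON provenance sidecar to `out_dir`:
#' `spectra.csv` (one row per replicate), `metadata.csv`, `reference.csv`
#' (noisy reference sugar measurements) and `truth.csv` (latent values).
#' The sidecar records the seed, the configurations and a config hash, so
#' two runs with the same seed produce byte-identical files. Existing files
#' are refused unless `force = TRUE`.
#'
#' @param kind `"natural"` or `"pedigree"`.
#' @param out_dir Output directory (created if missing).
#' @param n Number of samples (natural kind).
#' @param gconfig A [generator_config()].
#' @param pconfig A [pedigree_sim_config()] (pedigree kind).
#' @param seed Integer seed.
#' @param force Overwrite existing files.
#' @return Invisibly, a named list of the paths written.
#' @export
generate_dataset <- function(kind = c("natural", "pedigree"), out_dir,
                             n = 500, gconfig = generator_config(),
                             pconfig = pedigree_sim_config(), seed = 1,
                             force = FALSE) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c(spectra = "spectra.csv",
                                metadata = "metadata.csv",
                                reference = "reference.csv",
                                truth = "truth.csv",
                                provenance = "provenance.json"))
  names(paths) <- c("spectra", "metadata", "reference", "truth", "provenance")
  exists <- file.exists(paths)
  if (any(exists) && !force) {
    abort(paste0("refusing to overwrite ", paths[exists][1],
                 " (use force = TRUE)"),
          class = "pymbms_error_config")
  }
  if (kind == "natural") {
    truth <- sample_compositions(n, gconfig, seed = seed)
    spectra <- compose_spectra(truth, gconfig, seed = seed + 1L)
    reference <- nmr_measure(truth, gconfig, seed = seed + 2L)
    metadata <- tibble(
      sample_id = truth$sample_id,
      genotype_id = truth$sample_id,
      population = "natural",
      mother_id = NA_character_, father_id = NA_character_,
      field_row = NA_integer_, field_col = NA_integer_
    )
    configs <- list(generator = unclass(gconfig))
  } else {
    sim <- simulate_pedigree(pconfig, gconfig, seed = seed, spectra = TRUE)
    truth <- dplyr::left_join(sim$composition,
                              sim$records[c("sample_id", "genotype_id",
                                            "genotype_value", "value")],
                              by = "sample_id")
    spectra <- sim$spectra
    reference <- sim$reference
    metadata <- sim$metadata
    configs <- list(generator = unclass(gconfig),
                    pedigree = unclass(sim$config),
                    true_H2 = sim$true_H2)
  }
  write_spectra(spectra, paths[["spectra"]])
  write_sample_metadata(metadata, paths[["metadata"]])
  readr::write_csv(format_full_precision(reference), paths[["reference"]],
                   progress = FALSE)
  readr::write_csv(format_full_precision(truth), paths[["truth"]],
                   progress = FALSE)
  prov <- list(
    generator_version = as.character(utils::packageVersion("pymbms")),
    kind = kind, n = if (kind == "natural") n else nrow(truth),
    seed = seed, configs = configs,
    config_hash = config_hash(configs)
  )
  jsonlite::write_json(prov, paths[["provenance"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(as.list(paths))
}
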