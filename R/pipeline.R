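#' Pipeline stages over files
#'
#' File-level orchestration of the two workflows (natural-variant
#' calibration/validation and pedigree heritability), mirroring how the
#' method runs in production: every stage reads and writes delimited text
#' plus JSON models, logs to stderr, and is deterministic given its seed.
#' `pipeline_simulate()` wraps [generate_dataset()];
#' `pipeline_train()` normalizes, averages replicates, subsets the
#' calibration ids, fits the PLS1 calibration and reports cross-validation;
#' `pipeline_validate()` predicts a held-out set, computes validation
#' metrics and the side-by-side reduced-ion single-point estimates;
#' `pipeline_heritability()` wraps [heritability_pipeline()].
#'
#' A thin command-line wrapper over these functions ships at
#' `system.file("cli", "pymbms.R", package = "pymbms")`.
#'
#' @name pipeline
NULL

pipeline_log <- function(...) {
  message("[pymbms ", format(Sys.time(), "%H:%M:%S"), "] ", ...)
}

#' @rdname pipeline
#' @inheritParams generate_dataset
#' @export
pipeline_simulate <- function(kind, out_dir, n = 500,
                              gconfig = generator_config(),
                              pconfig = pedigree_sim_config(), seed = 1,
                              force = FALSE) {
  pipeline_log("simulate: kind=", kind, " seed=", seed,
               " config=", config_hash(list(gconfig, pconfig)))
  generate_dataset(kind, out_dir, n = n, gconfig = gconfig,
                   pconfig = pconfig, seed = seed, force = force)
}

#' @rdname pipeline
#' @param spectra_file,reference_file Paths written by
#'   [pipeline_simulate()] (or equivalent real data).
#' @param calibration_ids Character vector of sample ids to train on, or a
#'   path to a one-column text file of ids.
#' @param trait `"glucose"` or `"xylose"`.
#' @param n_factors Latent factor count; defaults to 4 for glucose, 5 for
#'   xylose.
#' @param normalization `"tic"` (default) or `"mean"`.
#' @param model_file Output JSON path for the fitted model.
#' @param cv Run leave-one-out/k-fold cross-validation on the calibration.
#' @param seed Seed for fold assignment.
#' @return `pipeline_train()` returns the fitted model (invisibly) with the
#'   CV table in its `cv` attribute.
#' @export
pipeline_train <- function(spectra_file, reference_file, calibration_ids,
                           trait = c("glucose", "xylose"), n_factors = NULL,
                           normalization = c("tic", "mean"),
                           model_file = NULL, cv = TRUE, seed = 1) {
  trait <- match.arg(trait)
  normalization <- match.arg(normalization)
  n_factors <- n_factors %||% if (trait == "glucose") 4L else 5L
  if (length(calibration_ids) == 1 && file.exists(calibration_ids)) {
    calibration_ids <- readLines(calibration_ids)
  }
  sp <- read_spectra(spectra_file)
  sp <- if (normalization == "tic") tic_normalize(sp) else mean_normalize(sp)
  avg <- average_replicates(sp)
  ref <- readr::read_csv(reference_file, show_col_types = FALSE,
                         progress = FALSE)
  unknown <- setdiff(calibration_ids, avg$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("calibration id not in spectra: ", unknown[1]),
          class = "pymbms_error_config")
  }
  col <- paste0(trait, "_dw_pct")
  cal <- avg[match(calibration_ids, avg$sample_id), ]
  y <- ref[[col]][match(calibration_ids, ref$sample_id)]
  if (anyNA(y)) {
    abort("calibration id missing from the reference table",
          class = "pymbms_error_config")
  }
  pipeline_log("train: trait=", trait, " n=", nrow(cal),
               " factors=", n_factors)
  fit <- fit_pls1(cal, y, n_factors)
  if (cv) {
    attr(fit, "cv") <- cross_validate(cal, y, max_factors = n_factors,
                                      seed = seed)
  }
  if (!is.null(model_file)) write_pls_model(fit, model_file)
  invisible(fit)
}

#' @rdname pipeline
#' @param model A fitted model or the path to a model JSON.
#' @param metadata_file Optional metadata CSV (passed through to outputs).
#' @param out_file Optional CSV path for the per-sample estimates.
#' @param single_point Also compute the reduced-ion single-point estimate
#'   using a noiseless standard composed from `gconfig`.
#' @param truth_file Optional truth CSV; when given, metrics are also
#'   reported against the latent truth.
#' @return `pipeline_validate()` returns a list: `estimates` (per-sample
#'   tibble), `metrics_reference` and (when truth is available)
#'   `metrics_truth`, each with one `validation_report` row per method.
#' @export
pipeline_validate <- function(model, spectra_file, reference_file,
                              trait = c("glucose", "xylose"),
                              metadata_file = NULL, truth_file = NULL,
                              out_file = NULL, single_point = TRUE,
                              gconfig = generator_config()) {
  trait <- match.arg(trait)
  if (is.character(model)) {
    if (!file.exists(model)) {
      abort(paste0("model file not found: ", model),
            class = "pymbms_error_config")
    }
    model <- read_pls_model(model)
  }
  sp <- tic_normalize(read_spectra(spectra_file))
  avg <- average_replicates(sp)
  ref <- readr::read_csv(reference_file, show_col_types = FALSE,
                         progress = FALSE)
  col <- paste0(trait, "_dw_pct")
  est <- tibble(
    sample_id = avg$sample_id,
    pls = predict(model, avg),
    measured = ref[[col]][match(avg$sample_id, ref$sample_id)]
  )
  if (single_point) {
    std <- standards_from_config(gconfig)[[trait]]
    est$single_point <- single_point_estimate(avg, std, col = ".e")$.e
  }
  metrics <- function(truthcol) {
    rows <- list(pls = validation_metrics(truthcol, est$pls))
    if (single_point) {
      rows$single_point <- validation_metrics(truthcol, est$single_point)
    }
    bind_rows(rows, .id = "method")
  }
  out <- list(estimates = est, metrics_reference = metrics(est$measured))
  if (!is.null(truth_file)) {
    tr <- readr::read_csv(truth_file, show_col_types = FALSE, progress = FALSE)
    out$metrics_truth <- metrics(tr[[col]][match(avg$sample_id, tr$sample_id)])
  }
  if (!is.null(out_file)) {
    readr::write_csv(format_full_precision(est), out_file, progress = FALSE)
  }
  pipeline_log("validate: trait=", trait, " n=", nrow(est), " PLS R2=",
               signif(out$metrics_reference$r2[1], 3))
  out
}

#' @rdname pipeline
#' @param tps Apply thin-plate-spline correction.
#' @param method `"moments"` or `"reml"`.
#' @param ions Optional channels for per-ion heritability.
#' @export
pipeline_heritability <- function(model, spectra_file, metadata_file,
                                  out_file = NULL, tps = TRUE,
                                  method = "moments", ions = NULL) {
  if (is.character(model)) {
    if (!file.exists(model)) {
      abort(paste0("model file not found: ", model),
            class = "pymbms_error_config")
    }
    model <- read_pls_model(model)
  }
  sp <- tic_normalize(read_spectra(spectra_file))
  meta <- read_sample_metadata(metadata_file)
  res <- heritability_pipeline(sp, meta, model, ions = ions, tps = tps,
                               method = method)
  if (!is.null(out_file)) {
    readr::write_csv(format_full_precision(res), out_file, progress = FALSE)
  }
  pipeline_log("heritability: ", nrow(res), " trait(s)")
  res
}
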