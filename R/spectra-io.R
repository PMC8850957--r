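#' Read and write spectra tables
#'
#' Spectra files are delimited text with one row per analytical replicate:
#' columns `sample_id`, `replicate_id`, then `mz_30` ... `mz_450`. The
#' delimiter is inferred from the extension (`.tsv` gives tab, anything else
#' comma) unless given. Round-tripping through `write_spectra()` then
#' `read_spectra()` reproduces intensities to full double precision and
#' metadata exactly.
#'
#' @param path File path.
#' @param normalization Normalization state to stamp on the table (files do
#'   not store it; the writer records it in a header comment only).
#' @param delim Field delimiter; inferred from the extension when `NULL`.
#' @return `read_spectra()` returns a spectra table; `write_spectra()` its
#'   input, invisibly.
#' @export
read_spectra <- function(path, normalization = c("raw", "mean", "tic"),
                         delim = NULL) {
  normalization <- match.arg(normalization)
  delim <- delim %||% infer_delim(path)
  # channels come in as text and are converted via strtod, which is
  # correctly rounded; this keeps write -> read exact at full precision
  df <- readr::read_delim(
    path, delim = delim, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
  df[] <- lapply(df, function(col) utils::type.convert(col, as.is = TRUE))
  as_spectra(df, normalization)
}

#' @rdname read_spectra
#' @param x A spectra table.
#' @export
write_spectra <- function(x, path, delim = NULL) {
  stopifnot(inherits(x, "mbms_spectra"))
  delim <- delim %||% infer_delim(path)
  writeLines(paste0("# normalization: ", normalization_state(x)), path)
  readr::write_delim(format_full_precision(as_tibble(x)), path, delim = delim,
                     append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(x)
}

infer_delim <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

# 17 significant digits round-trips doubles exactly
format_full_precision <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- NA_character_
    out
  })
  df
}

#' Read and write sample metadata
#'
#' Metadata files are CSV with columns `sample_id`, `genotype_id`,
#' `population` (`natural` or `pedigree`), `mother_id`, `father_id`,
#' `field_row`, `field_col`. Parent ids may be empty for natural accessions;
#' pedigree rows must carry both. Field coordinates are needed only when
#' spatial correction is requested downstream.
#'
#' @param path File path.
#' @return A tibble of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        comment = "#")
  validate_sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param x A metadata tibble.
#' @export
write_sample_metadata <- function(x, path) {
  readr::write_csv(validate_sample_metadata(x), path, progress = FALSE)
  invisible(x)
}

validate_sample_metadata <- function(df) {
  df <- as_tibble(df)
  need <- c("sample_id", "genotype_id", "population")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("metadata missing column(s): ", paste(miss, collapse = ", ")),
          class = "pymbms_error_parse")
  }
  if (!all(df$population %in% c("natural", "pedigree"))) {
    abort("population must be 'natural' or 'pedigree'",
          class = "pymbms_error_parse")
  }
  ped <- df$population == "pedigree"
  if (any(ped)) {
    if (!all(c("mother_id", "father_id") %in% names(df)) ||
        anyNA(df$mother_id[ped]) || anyNA(df$father_id[ped])) {
      abort("pedigree samples must carry mother_id and father_id",
            class = "pymbms_error_parse")
    }
  }
  df
}
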