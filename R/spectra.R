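#' Spectra tables
#'
#' A spectra table is a tibble with one row per analytical replicate (or per
#' sample, after [average_replicates()]), identifier columns `sample_id` and
#' `replicate_id`, and one intensity column per unit-mass channel, `mz_30`
#' through `mz_450` (421 channels). The table carries a `normalization`
#' attribute, one of `"raw"`, `"mean"` or `"tic"`, shared by all rows.
#'
#' `as_spectra()` validates a plain data frame and stamps the class;
#' `spectra_matrix()` extracts the intensity block as a numeric matrix with
#' `sample_id` row names (requires unique ids, i.e. replicate-averaged data
#' or single replicates).
#'
#' @param x A data frame with `sample_id`, optionally `replicate_id`, and
#'   columns `mz_30` ... `mz_450`.
#' @param normalization Normalization state of the intensities.
#' @return `as_spectra()` returns the validated spectra tibble;
#'   `spectra_matrix()` a samples-by-421 numeric matrix.
#' @examples
#' sp <- as_spectra(toy_spectrum(c(`126` = 1, `98` = 3)))
#' dim(spectra_matrix(sp))
#' @export
as_spectra <- function(x, normalization = c("raw", "mean", "tic")) {
  normalization <- if (is.null(attr(x, "normalization")) || !missing(normalization)) {
    match.arg(normalization)
  } else {
    attr(x, "normalization")
  }
  x <- as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    abort("spectra table needs a `sample_id` column", class = "pymbms_error_parse")
  }
  if (!"replicate_id" %in% names(x)) {
    x$replicate_id <- "r1"
  }
  check_channel_columns(names(x))
  missing_ch <- setdiff(mz_cols(), names(x))
  if (length(missing_ch) > 0) {
    abort(
      paste0("spectra table is missing ", length(missing_ch),
             " channel column(s), e.g. ", missing_ch[1]),
      class = "pymbms_error_parse"
    )
  }
  intens <- as.matrix(x[mz_cols()])
  if (!is.numeric(intens)) {
    abort("channel columns must be numeric", class = "pymbms_error_parse")
  }
  bad <- which(rowSums(intens < 0) > 0)
  if (length(bad) > 0) {
    abort(
      paste0("negative intensity in row ", bad[1], " (sample_id ",
             x$sample_id[bad[1]], ")"),
      class = "pymbms_error_parse"
    )
  }
  dup <- duplicated(x[c("sample_id", "replicate_id")])
  if (any(dup)) {
    abort(
      paste0("duplicate (sample_id, replicate_id): ",
             x$sample_id[dup][1], ", ", x$replicate_id[dup][1]),
      class = "pymbms_error_parse"
    )
  }
  meta_cols <- setdiff(names(x), mz_cols())
  x <- x[c(setdiff(meta_cols, mz_cols()), mz_cols())]
  new_spectra(x, normalization)
}

new_spectra <- function(x, normalization) {
  attr(x, "normalization") <- normalization
  class(x) <- unique(c("mbms_spectra", class(as_tibble(x))))
  x
}

# reject fractional-m/z column names such as mz_57.5 instead of rounding
check_channel_columns <- function(nms) {
  ch <- grep("^mz_", nms, value = TRUE)
  idx <- sub("^mz_", "", ch)
  frac <- ch[!grepl("^[0-9]+$", idx)]
  if (length(frac) > 0) {
    abort(
      paste0("fractional or malformed m/z column rejected: ", frac[1],
             " (channels are unit-mass integer bins)"),
      class = "pymbms_error_parse"
    )
  }
  out_of_range <- ch[as.integer(idx) < MZ_MIN | as.integer(idx) > MZ_MAX]
  if (length(out_of_range) > 0) {
    abort(
      paste0("m/z column outside 30..450 rejected: ", out_of_range[1]),
      class = "pymbms_error_parse"
    )
  }
  invisible(nms)
}

#' @rdname as_spectra
#' @export
spectra_matrix <- function(x) {
  stopifnot(inherits(x, "mbms_spectra"))
  if (anyDuplicated(x$sample_id) > 0) {
    abort(
      "duplicate sample_ids; average replicates before extracting the matrix",
      class = "pymbms_error_duplicate_samples"
    )
  }
  m <- as.matrix(x[mz_cols()])
  rownames(m) <- x$sample_id
  m
}

#' @export
print.mbms_spectra <- function(x, ...) {
  cat("# py-MBMS spectra: ", nrow(x), " row(s), ", n_channels(),
      " channels (m/z 30-450), normalization = ",
      attr(x, "normalization"), "\n", sep = "")
  NextMethod()
}

#' Normalization state of a spectra table
#' @param x A spectra table.
#' @return One of `"raw"`, `"mean"`, `"tic"`.
#' @export
normalization_state <- function(x) attr(x, "normalization") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize spectra
#'
#' `tic_normalize()` divides each replicate's intensities by its total ion
#' current so every row sums to 1. `mean_normalize()` divides by the mean
#' intensity over the 421 channels so every row has mean 1. Both preserve
#' relative channel proportions and are idempotent up to the scale they fix.
#'
#' @param x A spectra table (see [as_spectra()]).
#' @return The spectra table with rescaled intensities and updated
#'   normalization state.
#' @examples
#' sp <- as_spectra(toy_spectrum(c(`57` = 1, `73` = 3)))
#' rowSums(spectra_matrix(tic_normalize(sp)))
#' @export
tic_normalize <- function(x) {
  rescale_spectra(x, function(m) rowSums(m), "tic")
}

#' @rdname tic_normalize
#' @export
mean_normalize <- function(x) {
  rescale_spectra(x, function(m) rowMeans(m), "mean")
}

rescale_spectra <- function(x, denom_fun, state) {
  stopifnot(inherits(x, "mbms_spectra"))
  m <- as.matrix(x[mz_cols()])
  denom <- denom_fun(m)
  zero <- which(denom <= 0)
  if (length(zero) > 0) {
    abort(
      paste0("all-zero spectrum cannot be normalized (sample_id ",
             x$sample_id[zero[1]], ")"),
      class = "pymbms_error_invalid_spectrum"
    )
  }
  x[mz_cols()] <- m / denom
  new_spectra(x, state)
}

#' Average replicate spectra within samples
#'
#' Collapses a spectra table to one row per `sample_id` by channel-wise
#' arithmetic mean over its replicates, recording the replicate count in an
#' `n_replicates` column. Replicates are expected to be normalized first
#' (each pyrolysis run rescaled individually), so unequal total ion yields
#' between duplicate runs do not bias the mean; averaging raw spectra is
#' allowed but normalization does not commute with it in general.
#'
#' @param x A spectra table.
#' @return A spectra table with unique `sample_id`s, `replicate_id` dropped,
#'   and an `n_replicates` column.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "mbms_spectra"))
  state <- normalization_state(x)
  out <- x |>
    as_tibble() |>
    group_by(.data$sample_id) |>
    summarise(
      n_replicates = dplyr::n(),
      across(all_of(mz_cols()), mean),
      .groups = "drop"
    )
  new_spectra(out[c("sample_id", "n_replicates", mz_cols())], state)
}

#' Combine spectra tables
#'
#' Row-binds spectra tables, refusing to mix normalization states.
#'
#' @param ... Spectra tables.
#' @return A single spectra table.
#' @export
bind_spectra <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) > 0, all(vapply(parts, inherits, TRUE, "mbms_spectra")))
  states <- unique(vapply(parts, normalization_state, ""))
  if (length(states) > 1) {
    abort(
      paste0("cannot bind spectra with mixed normalization states: ",
             paste(states, collapse = ", ")),
      class = "pymbms_error_inconsistent_normalization"
    )
  }
  new_spectra(bind_rows(lapply(parts, as_tibble)), states)
}

#' Build a toy spectrum row
#'
#' Convenience constructor for examples and tests: a one-row spectra data
#' frame with the named channels set and all other channels zero.
#'
#' @param values Named numeric vector; names are integer m/z values.
#' @param sample_id,replicate_id Identifiers for the row.
#' @return A plain tibble suitable for [as_spectra()].
#' @examples
#' toy_spectrum(c(`154` = 2, `124` = 1))
#' @export
toy_spectrum <- function(values, sample_id = "s1", replicate_id = "r1") {
  stopifnot(is.numeric(values), !is.null(names(values)))
  v <- setNames(numeric(n_channels()), mz_cols())
  v[paste0("mz_", as.integer(names(values)))] <- values
  bind_cols(
    tibble(sample_id = sample_id, replicate_id = replicate_id),
    as_tibble(as.list(v))
  )
}
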