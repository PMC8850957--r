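#' Sum diagnostic-ion intensities
#'
#' Adds an `ion_sum` column: the sum of each row's intensities over the
#' member channels of `ions`. An empty set sums to 0. Sums over disjoint
#' sets are additive.
#'
#' @param x A spectra table.
#' @param ions An [ion_set()].
#' @return `x` with an `ion_sum` column appended (name taken from
#'   `col`).
#' @param col Name for the output column.
#' @examples
#' sp <- tic_normalize(as_spectra(toy_spectrum(c(`126` = 0.4, `300` = 0.6))))
#' ion_sum(sp, c6_ions())$ion_sum
#' @export
ion_sum <- function(x, ions, col = "ion_sum") {
  stopifnot(inherits(x, "mbms_spectra"), inherits(ions, "ion_set"))
  m <- as.matrix(x[mz_cols()])
  s <- if (length(ions$members) == 0) {
    rep(0, nrow(m))
  } else {
    rowSums(m[, paste0("mz_", ions$members), drop = FALSE])
  }
  x[[col]] <- unname(s)
  x
}

#' Syringyl/guaiacyl ratio
#'
#' The S/G ratio is the sum of syringyl-labeled ion intensities divided by
#' the sum of guaiacyl-labeled ones, per spectrum. It is invariant to any
#' global rescaling of a spectrum, so the normalization choice does not
#' affect it.
#'
#' @param x A spectra table.
#' @param ions Ion set carrying S/G sublabels; defaults to the shipped
#'   lignin set.
#' @param on_zero_g What to do when a spectrum has zero guaiacyl intensity:
#'   `"error"` (default) or `"na"` (record `NA` with a warning).
#' @return `x` with an `sg_ratio` column.
#' @examples
#' sp <- as_spectra(toy_spectrum(c(`154` = 2, `124` = 1)))
#' sg_ratio(sp)$sg_ratio
#' @export
sg_ratio <- function(x, ions = lignin_ions(), on_zero_g = c("error", "na")) {
  on_zero_g <- match.arg(on_zero_g)
  s_sum <- ion_sum(x, ion_set("S", sg_members(ions, "S")), col = ".s")$.s
  g_sum <- ion_sum(x, ion_set("G", sg_members(ions, "G")), col = ".g")$.g
  zero <- g_sum <= 0
  if (any(zero)) {
    if (on_zero_g == "error") {
      abort(
        paste0("S/G ratio undefined: zero guaiacyl ion sum (sample_id ",
               x$sample_id[which(zero)[1]], ")"),
        class = "pymbms_error_undefined_ratio"
      )
    }
    warn(paste0("S/G undefined for ", sum(zero), " spectrum(s); recorded as NA"))
  }
  x$sg_ratio <- ifelse(zero, NA_real_, s_sum / g_sum)
  x
}

#' Reference standard for single-point estimation
#'
#' Binds a normalized spectrum of a material of known composition (e.g. a
#' standard of known Klason lignin content) to its reference value, for use
#' by [single_point_estimate()].
#'
#' @param spectrum A one-row spectra table, normalized.
#' @param known_value Reference composition of the standard (percent of dry
#'   weight for lignin and sugars).
#' @param target One of `"lignin"`, `"glucose"`, `"xylose"`.
#' @return A `reference_standard` object.
#' @export
reference_standard <- function(spectrum, known_value,
                               target = c("lignin", "glucose", "xylose")) {
  target <- match.arg(target)
  stopifnot(inherits(spectrum, "mbms_spectra"), nrow(spectrum) == 1)
  if (!is.numeric(known_value) || known_value <= 0) {
    abort("known_value must be positive", class = "pymbms_error_invalid_standard")
  }
  structure(
    list(spectrum = spectrum, known_value = known_value, target = target),
    class = "reference_standard"
  )
}

#' Single-point (response-factor) composition estimate
#'
#' Scales each sample's diagnostic-ion sum by a single reference standard:
#' `estimate = known_value * ion_sum(sample) / ion_sum(standard)`. Exactly
#' linear in the sample's ion sum. Sample spectra and the standard must
#' share a normalization state.
#'
#' @param x A spectra table.
#' @param standard A [reference_standard()].
#' @param ions Ion set to sum; defaults to the set conventional for the
#'   standard's target (lignin set, C6 for glucose, C5 for xylose).
#' @param col Name for the estimate column.
#' @return `x` with the estimate column appended.
#' @export
single_point_estimate <- function(x, standard, ions = NULL, col = "estimate") {
  stopifnot(inherits(standard, "reference_standard"))
  ions <- ions %||% switch(standard$target,
    lignin = lignin_ions(), glucose = c6_ions(), xylose = c5_ions()
  )
  if (!identical(normalization_state(x), normalization_state(standard$spectrum))) {
    abort("sample spectra and standard differ in normalization state",
          class = "pymbms_error_inconsistent_normalization")
  }
  std_sum <- ion_sum(standard$spectrum, ions, col = ".s")$.s
  if (std_sum <= 0) {
    abort("standard has zero ion sum over the estimation set",
          class = "pymbms_error_invalid_standard")
  }
  s <- ion_sum(x, ions, col = ".s")$.s
  x[[col]] <- standard$known_value * s / std_sum
  x
}

#' Batch single-point scoring
#'
#' Applies the single-point estimators and the S/G ratio across a
#' replicate-averaged spectra table, producing one composition-estimate row
#' per sample. Undefined S/G ratios become missing values with a warning
#' rather than an error.
#'
#' @param x A replicate-averaged, normalized spectra table.
#' @param standards Named list of [reference_standard()] objects; names among
#'   `"lignin"`, `"glucose"`, `"xylose"`. Targets without a standard are
#'   omitted from the output.
#' @param sg Whether to compute the S/G ratio.
#' @return A tibble with `sample_id`, one column per scored trait
#'   (`lignin_pct`, `glucose_dw_pct`, `xylose_dw_pct`, `sg_ratio`) and
#'   `method = "single_point"`.
#' @export
score_set <- function(x, standards = list(), sg = TRUE) {
  stopifnot(inherits(x, "mbms_spectra"))
  out <- tibble(sample_id = x$sample_id)
  col_for <- c(lignin = "lignin_pct", glucose = "glucose_dw_pct",
               xylose = "xylose_dw_pct")
  for (tgt in names(standards)) {
    out[[col_for[[tgt]]]] <-
      single_point_estimate(x, standards[[tgt]], col = ".est")$.est
  }
  if (sg) {
    out$sg_ratio <- sg_ratio(x, on_zero_g = "na")$sg_ratio
  }
  out$method <- "single_point"
  out
}

#' Summary statistics for composition estimates
#'
#' Mean, maximum, minimum, range and standard deviation per trait column, in
#' the layout conventional for py-MBMS composition tables.
#'
#' @param estimates Output of [score_set()] (or any tibble of per-sample
#'   trait columns).
#' @param traits Columns to summarise; defaults to the scored trait columns
#'   present.
#' @return A tibble with one row per statistic and one column per trait.
#' @export
composition_summary <- function(estimates, traits = NULL) {
  traits <- traits %||% intersect(
    c("lignin_pct", "glucose_dw_pct", "xylose_dw_pct", "sg_ratio"),
    names(estimates)
  )
  stat_tbl <- tibble(
    statistic = c("mean", "max", "min", "range", "sd")
  )
  for (tr in traits) {
    v <- estimates[[tr]]
    v <- v[!is.na(v)]
    stat_tbl[[tr]] <- c(mean(v), max(v), min(v), max(v) - min(v), sd(v))
  }
  stat_tbl
}
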