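#' Thin-plate-spline correction of field microspatial trends
#'
#' Fits a smooth thin-plate-spline surface `f(field_row, field_col)` to the
#' phenotype values of a field trial, subtracts it, and re-adds the grand
#' mean, removing microspatial environmental trends (soil, moisture,
#' instrument drift mapped onto planting order) while leaving the grand mean
#' unchanged. Smoothing is chosen by generalized cross-validation unless a
#' fixed smoothing parameter is supplied; spatially unstructured data
#' therefore come back essentially untouched.
#'
#' The surface is `mgcv::gam(value ~ s(field_row, field_col, bs = "tp"))`
#' with basis dimension `knots` and knot thinning to at most `max_knots`
#' distinct locations (the spline solve is cubic in the knot count).
#'
#' @param records Tibble with `field_row`, `field_col` and the value column.
#' @param value Name of the phenotype column (string). Default `"value"`.
#' @param smoothing `"gcv"` or `"fixed"`.
#' @param lambda Smoothing parameter when `smoothing = "fixed"` (> 0).
#' @param knots Basis dimension of the spline.
#' @param max_knots Upper bound on distinct knot locations.
#' @return `records` with the value column replaced by the corrected values;
#'   the removed surface is kept in a `spatial_effect` column and the gam
#'   fit in the `tps_fit` attribute.
#' @export
tps_correct <- function(records, value = "value",
                        smoothing = c("gcv", "fixed"), lambda = NULL,
                        knots = 60, max_knots = 200) {
  smoothing <- match.arg(smoothing)
  stopifnot(all(c("field_row", "field_col", value) %in% names(records)))
  coords <- unique(records[c("field_row", "field_col")])
  if (nrow(coords) < 2) {
    abort("all records share one field coordinate; no surface is estimable",
          class = "pymbms_error_degenerate_geometry")
  }
  if (smoothing == "fixed" && (is.null(lambda) || lambda <= 0)) {
    abort("fixed smoothing needs lambda > 0", class = "pymbms_error_config")
  }
  y <- records[[value]]
  if (sd(y) == 0) {
    # constant phenotypes carry no spatial signal; return unchanged
    records$spatial_effect <- 0
    return(records)
  }
  k <- min(knots, nrow(coords) - 1)
  d <- data.frame(.y = y, field_row = records$field_row,
                  field_col = records$field_col)
  fit <- mgcv::gam(
    .y ~ s(field_row, field_col, bs = "tp", k = k,
           xt = list(max.knots = max_knots)),
    data = d,
    sp = if (smoothing == "fixed") lambda else NULL,
    method = "GCV.Cp"
  )
  surface <- fitted(fit) - mean(y)
  records[[value]] <- y - surface
  records$spatial_effect <- surface
  attr(records, "tps_fit") <- fit
  records
}
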