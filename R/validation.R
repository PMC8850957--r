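#' Validation statistics for measured vs. predicted values
#'
#' The calibration/validation report used throughout: Pearson correlation
#' (PCC), its square reported as R-squared, root-mean-square error in trait
#' units, and per-sample relative errors `(predicted - measured)/measured *
#' 100` summarised as min, max, mean absolute, and SD. Reading R-squared as
#' the squared correlation of measured and predicted keeps R2 and PCC
#' mutually consistent (e.g. PCC 0.86 pairs with R2 0.74).
#'
#' A constant vector makes the correlation undefined; it is reported as 0
#' with `degenerate = TRUE` rather than propagating `NaN`. Samples with a
#' zero measured value are excluded from the relative-error statistics (with
#' a warning) but kept in RMSE and PCC.
#'
#' @param measured Reference trait values (length >= 3).
#' @param predicted Model predictions, same length.
#' @return A one-row `validation_report` tibble: `n`, `r2`, `pcc`, `rmse`,
#'   `err_min_pct`, `err_max_pct`, `err_mean_abs_pct`, `err_sd_pct`,
#'   `degenerate`.
#' @examples
#' validation_metrics(c(10, 20), c(11, 18))
#' @export
validation_metrics <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted), length(measured) >= 2)
  degenerate <- sd(measured) == 0 || sd(predicted) == 0
  pcc <- if (degenerate) 0 else cor(measured, predicted)
  rmse <- sqrt(mean((predicted - measured)^2))
  ok <- measured != 0
  if (!all(ok)) {
    warn(paste0(sum(!ok), " sample(s) with zero measured value excluded from ",
                "relative-error statistics"))
  }
  rel <- (predicted[ok] - measured[ok]) / measured[ok] * 100
  out <- tibble(
    n = length(measured),
    r2 = pcc^2,
    pcc = pcc,
    rmse = rmse,
    err_min_pct = min(rel),
    err_max_pct = max(rel),
    err_mean_abs_pct = mean(abs(rel)),
    err_sd_pct = sd(rel),
    degenerate = degenerate
  )
  class(out) <- c("validation_report", class(out))
  out
}

#' Write a validation report
#'
#' CSV of the metrics plus a short human-readable text summary alongside
#' (same path with `.txt` appended) when `summary = TRUE`.
#'
#' @param report A [validation_metrics()] tibble.
#' @param path Output CSV path.
#' @param summary Also write the text summary.
#' @export
write_validation_report <- function(report, path, summary = TRUE) {
  readr::write_csv(as_tibble(report), path, progress = FALSE)
  if (summary) {
    lines <- c(
      sprintf("n = %d", report$n),
      sprintf("R2 (measured vs predicted) = %.4f", report$r2),
      sprintf("PCC = %.4f%s", report$pcc,
              if (report$degenerate) " (degenerate: constant vector)" else ""),
      sprintf("RMSE = %.4g (trait units)", report$rmse),
      sprintf("relative error: %.1f%% to %+.1f%%, mean |%.1f%%| (SD %.1f%%)",
              report$err_min_pct, report$err_max_pct,
              report$err_mean_abs_pct, report$err_sd_pct)
    )
    writeLines(lines, paste0(path, ".txt"))
  }
  invisible(report)
}
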