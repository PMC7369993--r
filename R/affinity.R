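#' Convert an experimental affinity to a binding free energy
#'
#' Treats IC50 and Ki as surrogates for the dissociation constant and
#' converts to a standard binding free energy,
#' `dG = RT ln(c / c0)` with `c0 = 1 M`, so a 1 M affinity maps to exactly
#' zero and any sub-molar affinity to a negative free energy.
#'
#' @param value affinity value, positive; vectorised.
#' @param unit concentration unit: `"M"`, `"mM"`, `"uM"` (or `"µM"`),
#'   `"nM"`; recycled along `value`.
#' @param kind `"IC50"` or `"Ki"`; both are converted identically and the
#'   argument exists to keep provenance explicit.
#' @param temperature temperature in Kelvin.
#' @return binding free energy in kcal/mol.
#' @examples
#' dg_from_affinity(11.0, "uM")  # about -6.76
#' dg_from_affinity(0.08, "nM")  # about -13.77
#' @export
dg_from_affinity <- function(value, unit, kind = c("IC50", "Ki"),
                             temperature = 298) {
  kind <- match.arg(kind)
  if (!is.numeric(value) || length(value) == 0L || anyNA(value) ||
      any(value <= 0)) {
    .fail("affinity values must be positive numbers",
          "felbind_domain_error")
  }
  fac <- .unit_factor(unit)
  kT(temperature) * log(value * fac)
}

## Molar scale factor for an affinity unit; errors on unknown units.
.unit_factor <- function(unit) {
  lut <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)
  key <- gsub("µ", "u", as.character(unit)) # accept micro sign
  bad <- !(key %in% names(lut))
  if (any(bad)) {
    .fail(sprintf("unknown affinity unit: %s",
                  paste(unique(unit[bad]), collapse = ", ")),
          "felbind_validation_error")
  }
  unname(lut[key])
}

#' Benchmark error metrics against experimental free energies
#'
#' Computes the standard evaluation metrics for predicted versus
#' experimental binding free energies: mean absolute error, root mean
#' square error, Pearson correlation and Spearman rank correlation
#' (average ranks on ties).
#'
#' @param pred,ref numeric vectors of equal length (at least 2), kcal/mol.
#' @return object of class `evaluation_report`: list with `mae`, `rmse`,
#'   `pearson`, `spearman`, `n` and `per_complex_error` (`pred - ref`).
#' @examples
#' evaluate_predictions(c(-6.5, -7.2, -9.1), c(-6.8, -7.0, -8.5))
#' @export
evaluate_predictions <- function(pred, ref) {
  if (!is.numeric(pred) || !is.numeric(ref) ||
      length(pred) != length(ref)) {
    .fail("`pred` and `ref` must be numeric vectors of equal length",
          "felbind_input_error")
  }
  if (length(pred) < 2L) {
    .fail("at least two prediction/reference pairs are required",
          "felbind_input_error")
  }
  if (anyNA(pred) || anyNA(ref)) {
    .fail("missing values are not allowed", "felbind_input_error")
  }
  err <- pred - ref
  structure(list(
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    pearson = stats::cor(pred, ref, method = "pearson"),
    spearman = stats::cor(pred, ref, method = "spearman"),
    n = length(pred),
    per_complex_error = err),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat(sprintf(
    paste0("<evaluation_report> n = %d\n  MAE  %.*f kcal/mol\n  RMSE ",
           "%.*f kcal/mol\n  Pearson  %.*f\n  Spearman %.*f\n"),
    x$n, digits, x$mae, digits, x$rmse, digits, x$pearson,
    digits, x$spearman))
  invisible(x)
}

#' Count predictions within a threshold of experiment
#'
#' @param pred,ref numeric vectors of equal length, kcal/mol.
#' @param threshold inclusive absolute-error threshold in kcal/mol
#'   (default 2).
#' @return integer count of `|pred - ref| <= threshold`.
#' @export
count_within <- function(pred, ref, threshold = 2) {
  if (!is.numeric(pred) || !is.numeric(ref) ||
      length(pred) != length(ref) || length(pred) < 1L) {
    .fail("`pred` and `ref` must be numeric vectors of equal length",
          "felbind_input_error")
  }
  if (!.is_number(threshold) || threshold < 0) {
    .fail("`threshold` must be a non-negative number",
          "felbind_domain_error")
  }
  sum(abs(pred - ref) <= threshold)
}
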