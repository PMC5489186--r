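#' WHO iodine-status category labels
#'
#' Ordered category labels used throughout the package: deficient
#' (< 100 ug I/L), adequate (100-299 ug I/L, grouping the WHO "adequate" and
#' "above requirements" bands), excessive (>= 300 ug I/L).
#'
#' @format Character vector of length 3, in increasing order of iodine level.
#' @export
iodine_categories <- c("deficient", "adequate", "excessive")

#' WHO category thresholds (ug I/L)
#'
#' Lower bounds of the adequate and excessive bands. Both thresholds are
#' closed on the left: a concentration exactly at a threshold falls in the
#' higher category.
#'
#' @format Named numeric vector with elements `adequate` (100) and
#'   `excessive` (300).
#' @export
who_thresholds <- c(adequate = 100, excessive = 300)

#' Categorize a urinary iodine concentration
#'
#' Maps concentrations to the three-way WHO classification used for
#' population iodine surveys: `deficient` below 100 ug I/L, `adequate` for
#' 100-299 ug I/L, `excessive` at or above 300 ug I/L. Intervals are closed
#' on the left, so 100 is adequate and 300 is excessive. Negative
#' concentrations (which arise from calibration inversion of weakly coloured
#' zones) are categorized as deficient; quantitative metrics flag and exclude
#' them separately (see [accuracy_metrics()]).
#'
#' @param conc Numeric vector of concentrations in ug I/L. Must be finite.
#' @return Factor with levels `deficient < adequate < excessive`.
#' @examples
#' categorize(c(0, 110, 300))
#' @export
categorize <- function(conc) {
  if (!is.numeric(conc) || length(conc) == 0) {
    stop("`conc` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(conc))) {
    stop("invalid measurement: non-finite concentration", call. = FALSE)
  }
  idx <- findInterval(conc, who_thresholds) + 1L
  factor(iodine_categories[idx], levels = iodine_categories, ordered = TRUE)
}

as_iodine_category <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (!all(x %in% iodine_categories)) {
    stop("unknown iodine category; expected one of: ",
         paste(iodine_categories, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = iodine_categories, ordered = TRUE)
}
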