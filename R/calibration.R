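#' Fit the per-card calibration curve
#'
#' Ordinary least-squares line of red-minus-blue score against concentration
#' through the three on-card internal standards (0, 100, 300 ug I/L). The
#' single residual degree of freedom yields a standard error for the
#' intercept, which is the natural yardstick for deciding whether small
#' negative inversions are within calibration error. A near-zero slope marks
#' the card as degenerate (unusable) rather than raising an error.
#'
#' @param conc Standard concentrations; must be exactly 0, 100 and 300
#'   (any order).
#' @param score The three standards' red-minus-blue scores.
#' @param slope_epsilon Absolute slope (score units per ug I/L) below which
#'   the calibration is flagged degenerate.
#' @return An object of class `calibration_curve` with elements `slope`,
#'   `intercept`, `intercept_se`, `r_squared`, `standard_points`,
#'   `degenerate`.
#' @examples
#' fit_calibration(c(0, 100, 300), c(-50, 0, 100))  # slope 0.5, intercept -50
#' @export
fit_calibration <- function(conc, score, slope_epsilon = 1e-3) {
  if (length(conc) != 3L || length(score) != 3L) {
    stop("calibration needs exactly the three on-card standards", call. = FALSE)
  }
  if (!identical(sort(as.numeric(conc)), c(0, 100, 300))) {
    stop("standard concentrations must be exactly 0, 100 and 300 ug I/L",
         call. = FALSE)
  }
  if (any(!is.finite(score))) {
    stop("standard scores must be finite", call. = FALSE)
  }
  fit <- lm(score ~ conc, data = data.frame(conc = as.numeric(conc),
                                            score = as.numeric(score)))
  cf <- coef(fit)
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  se <- sm$coefficients["(Intercept)", "Std. Error"]
  if (!is.finite(se)) se <- 0
  structure(
    list(slope = unname(cf["conc"]), intercept = unname(cf["(Intercept)"]),
         intercept_se = unname(se),
         r_squared = if (is.finite(r2)) r2 else NA_real_,
         standard_points = data.frame(conc = as.numeric(conc),
                                      score = as.numeric(score)),
         degenerate = abs(unname(cf["conc"])) < slope_epsilon),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> score = %.4f * conc + %.2f (r2 %s%s)\n",
              x$slope, x$intercept,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' Invert the calibration curve for a sample score
#'
#' Computes `conc = (score - intercept) / slope` and flags out-of-range
#' inversions: negative estimates (`below_range_negative`, typically within
#' the intercept's error) and estimates above the 300 ug I/L calibration
#' ceiling (`above_range_extrapolated`). The value is always returned
#' alongside its flags, never clipped, so categorical analyses can keep all
#' reads while quantitative metrics apply the exclusion rules.
#'
#' @param score Numeric score(s).
#' @param curve A `calibration_curve`.
#' @return Data frame with columns `estimate`, `below_range_negative`,
#'   `above_range_extrapolated`.
#' @examples
#' cv <- fit_calibration(c(0, 100, 300), c(-50, 0, 100))
#' quantify(25, cv)  # 150 ug I/L
#' @export
quantify <- function(score, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$degenerate) {
    stop("unusable card: degenerate (flat) calibration curve", call. = FALSE)
  }
  est <- (score - curve$intercept) / curve$slope
  data.frame(estimate = est,
             below_range_negative = est < 0,
             above_range_extrapolated = est > 300)
}

#' Pool replicate concentration estimates
#'
#' Combines the (up to three) replicate circles of one sample row into a
#' single estimate. The default pool is the arithmetic mean; the median is
#' available as a robust alternative. Range flags propagate: the pooled read
#' is flagged if any replicate was flagged, or if the pooled value itself
#' falls outside 0-300 ug I/L.
#'
#' @param estimates Either the data frame returned by [quantify()] or a
#'   numeric vector of replicate concentrations (1-3 values).
#' @param method `"mean"` (default) or `"median"`.
#' @return One-row data frame with `pooled_estimate`,
#'   `below_range_negative`, `above_range_extrapolated`.
#' @examples
#' pool_replicates(c(140, 150, 160))  # 150
#' @export
pool_replicates <- function(estimates, method = c("mean", "median")) {
  method <- match.arg(method)
  if (is.data.frame(estimates)) {
    vals <- estimates$estimate
    neg <- estimates$below_range_negative
    ext <- estimates$above_range_extrapolated
  } else {
    vals <- as.numeric(estimates)
    neg <- vals < 0
    ext <- vals > 300
  }
  if (length(vals) == 0L) stop("no replicates to pool", call. = FALSE)
  if (length(vals) > 3L) {
    stop("a sample row carries at most three replicate circles", call. = FALSE)
  }
  if (any(!is.finite(vals))) stop("replicates must be finite", call. = FALSE)
  pooled <- if (method == "mean") mean(vals) else median(vals)
  data.frame(pooled_estimate = pooled,
             below_range_negative = pooled < 0 || any(neg),
             above_range_extrapolated = pooled > 300 || any(ext))
}
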