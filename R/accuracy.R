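#' Quantitative accuracy metrics with calibration-range exclusions
#'
#' Applies the card's exclusion bookkeeping and computes the quantitative
#' validation metrics. Reads flagged above the 300 ug I/L calibration
#' ceiling (extrapolated) or below zero (negative inversions, within the
#' intercept's error) are excluded; the remainder (`n_in_range`) feed:
#' \itemize{
#'   \item accuracy — mean absolute error, overall and per analyst;
#'   \item system bias — mean signed error, overall and per analyst;
#'   \item inter-operator precision — mean absolute difference between the
#'     two analysts' estimates of the same solution, over solutions where
#'     both estimates are in range;
#'   \item inter-device precision — standard deviation over replicate cards
#'     of one solution, when such replicates are supplied separately.
#' }
#'
#' @param records Data frame with columns `true_conc`, `estimate`,
#'   `below_range_negative`, `above_range_extrapolated`, and optionally
#'   `analyst_id` and `solution_id` (needed for per-analyst bias and
#'   inter-operator precision).
#' @param inter_device Optional numeric vector of replicate estimates of a
#'   single solution (e.g. five cards of a 150 ug I/L standard) for the
#'   inter-device standard deviation.
#' @return A list of class `accuracy_report`: `n_total`, `n_in_range`,
#'   `excluded_above_range`, `excluded_negative`, `mae`, `bias`,
#'   `per_analyst` (data frame of n/mae/bias), `inter_operator_mean_abs_diff`
#'   (`NA` without two analysts), `inter_device_sd` (`NA` without
#'   `inter_device`).
#' @export
accuracy_metrics <- function(records, inter_device = NULL) {
  need <- c("true_conc", "estimate", "below_range_negative",
            "above_range_extrapolated")
  if (!is.data.frame(records) || !all(need %in% names(records)) ||
      nrow(records) == 0L) {
    stop("records must be a non-empty data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  excl_above <- records$above_range_extrapolated
  excl_neg <- records$below_range_negative & !excl_above
  in_range <- !excl_above & !excl_neg
  if (!any(in_range)) {
    stop("no in-range records: all reads were excluded", call. = FALSE)
  }
  r <- records[in_range, ]
  err <- r$estimate - r$true_conc

  per_analyst <- NULL
  if ("analyst_id" %in% names(r)) {
    per_analyst <- do.call(rbind, lapply(split(err, r$analyst_id), function(e) {
      data.frame(n = length(e), mae = mean(abs(e)), bias = mean(e))
    }))
    per_analyst <- cbind(analyst_id = rownames(per_analyst), per_analyst)
    rownames(per_analyst) <- NULL
  }

  inter_op <- NA_real_
  n_pairs <- 0L
  if (all(c("analyst_id", "solution_id") %in% names(r)) &&
      length(unique(r$analyst_id)) >= 2L) {
    analysts <- sort(unique(r$analyst_id))[1:2]
    a1 <- r[r$analyst_id == analysts[1], c("solution_id", "estimate")]
    a2 <- r[r$analyst_id == analysts[2], c("solution_id", "estimate")]
    both <- merge(a1, a2, by = "solution_id")
    if (nrow(both) > 0L) {
      inter_op <- mean(abs(both$estimate.x - both$estimate.y))
      n_pairs <- nrow(both)
    }
  }

  structure(
    list(n_total = nrow(records), n_in_range = sum(in_range),
         excluded_above_range = sum(excl_above),
         excluded_negative = sum(excl_neg),
         mae = mean(abs(err)), bias = mean(err),
         per_analyst = per_analyst,
         inter_operator_mean_abs_diff = inter_op,
         inter_operator_n_pairs = n_pairs,
         inter_device_sd = if (is.null(inter_device)) NA_real_
                           else sd(inter_device)),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %d/%d reads in calibration range (%d above-range, %d negative excluded)\n",
              x$n_in_range, x$n_total, x$excluded_above_range,
              x$excluded_negative))
  cat(sprintf("  MAE %.1f ug I/L, bias %+.1f ug I/L\n", x$mae, x$bias))
  if (!is.na(x$inter_operator_mean_abs_diff)) {
    cat(sprintf("  inter-operator |diff| %.1f ug I/L (n = %d pairs)\n",
                x$inter_operator_mean_abs_diff, x$inter_operator_n_pairs))
  }
  if (!is.na(x$inter_device_sd)) {
    cat(sprintf("  inter-device sd %.1f ug I/L\n", x$inter_device_sd))
  }
  invisible(x)
}

#' Population iodine status from survey estimates
#'
#' A population's iodine status is judged by the median urinary iodine
#' concentration of the survey, categorized with the WHO thresholds. All
#' submitted estimates enter the median — including flagged above-range or
#' negative reads, since silently dropping excessive readings would bias a
#' survey median downward. The even-n median is the midpoint of the central
#' order statistics.
#'
#' @param estimates Numeric vector of per-card concentration estimates
#'   (ug I/L).
#' @return A list of class `population_status`: `median_conc`, `category`,
#'   `n`.
#' @examples
#' population_status(c(150, 175, 200))  # median 175, adequate
#' @export
population_status <- function(estimates) {
  if (length(estimates) == 0L || any(!is.finite(estimates))) {
    stop("estimates must be a non-empty vector of finite values",
         call. = FALSE)
  }
  med <- median(estimates)
  structure(list(median_conc = med, category = categorize(med),
                 n = length(estimates)),
            class = "population_status")
}

#' @export
print.population_status <- function(x, ...) {
  cat(sprintf("<population_status> median %.1f ug I/L over n = %d: %s\n",
              x$median_conc, x$n, as.character(x$category)))
  invisible(x)
}

#' Full validation report for an analyzed study
#'
#' Assembles the validation layer from a per-card results table (see
#' [analyze_study()]): visual and computer confusion matrices against truth,
#' percent correct, Cohen's kappa under all three weightings, the accuracy
#' report with range exclusions, and the median-based population status
#' (computed from the computer estimates, alongside the true median).
#'
#' @param results Data frame from [analyze_study()] (needs `true_category`,
#'   `category`, `visual_category`, `true_conc`, `estimate`, flags, ids).
#' @param inter_device Optional replicate estimates for inter-device
#'   precision (see [accuracy_metrics()]).
#' @return A list of class `validation_report`.
#' @export
validate_study <- function(results, inter_device = NULL) {
  cm_vis <- confusion_matrix(results$true_category, results$visual_category)
  cm_comp <- confusion_matrix(results$true_category, results$category)
  kappas <- function(cm) {
    sapply(c("none", "linear", "quadratic"),
           function(w) cohens_kappa(cm, w)$kappa)
  }
  structure(
    list(visual = list(confusion = cm_vis,
                       percent_correct = percent_correct(cm_vis),
                       kappa = kappas(cm_vis)),
         computer = list(confusion = cm_comp,
                         percent_correct = percent_correct(cm_comp),
                         kappa = kappas(cm_comp)),
         accuracy = accuracy_metrics(results, inter_device = inter_device),
         population = list(
           estimated = population_status(results$estimate),
           true = population_status(results$true_conc))),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("== Validation report ==\n")
  for (side in c("visual", "computer")) {
    s <- x[[side]]
    cat(sprintf("%s analysis: %.1f%% correct; kappa %.3f (unweighted), %.3f (linear), %.3f (quadratic)\n",
                side, s$percent_correct, s$kappa["none"], s$kappa["linear"],
                s$kappa["quadratic"]))
  }
  print(x$accuracy)
  cat("population status (estimated): ")
  print(x$population$estimated)
  cat("population status (true):      ")
  print(x$population$true)
  invisible(x)
}
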