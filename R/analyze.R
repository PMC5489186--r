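#' Analyze one card photograph
#'
#' Full single-card pipeline: register the image against the layout via the
#' fiducials, extract per-zone channel means and red-minus-blue scores, fit
#' the calibration line through the three internal standards, invert it for
#' each sample zone, pool the replicate rows, and attach both the computed
#' category (thresholds applied to the pooled estimate) and the simulated
#' visual read (nearest-standard colour comparison).
#'
#' The six sample zones are treated as two replicate rows of three circles
#' each (`sample_1..3` and `sample_4..6` in the default layout); the
#' card-level estimate pools all usable sample zones.
#'
#' @param image A `card_image` or path to a PNG/TIFF file.
#' @param layout The `card_layout`.
#' @param erosion Zone-sampling erosion fraction (see
#'   [extract_zone_stats()]).
#' @param pool Replicate pooling rule, `"mean"` or `"median"`.
#' @return A list of class `card_result`: `transform`, `readings`,
#'   `calibration`, `zones` (per-sample-zone estimates and categories),
#'   `estimate` (card-level pooled concentration), `flags`, `category`,
#'   `visual_category` (majority over sample zones, ties toward the lower
#'   category).
#' @export
analyze_card <- function(image, layout = default_card_layout(),
                         erosion = 0.15, pool = c("mean", "median")) {
  pool <- match.arg(pool)
  if (is.character(image)) image <- read_card_image(image)
  tr <- detect_fiducials(image, layout)
  readings <- extract_zone_stats(image, layout, tr, erosion = erosion)

  std <- readings[readings$role == "standard" & !readings$out_of_frame, ]
  if (nrow(std) != 3L) {
    stop("unusable card: not all three standard zones could be read",
         call. = FALSE)
  }
  std <- std[order(std$standard_conc), ]
  curve <- fit_calibration(std$standard_conc, std$score)
  if (curve$degenerate) {
    stop("unusable card: degenerate (flat) calibration curve", call. = FALSE)
  }

  smp <- readings[readings$role == "sample" & !readings$out_of_frame, ]
  q <- quantify(smp$score, curve)
  zones <- cbind(smp[, c("zone_id", "score")], q)
  zones$category <- categorize(zones$estimate)
  zones$visual_category <- simulated_visual_read(smp, std)

  pooled <- pool_replicates_any(q, pool)
  vis_tab <- table(factor(zones$visual_category, levels = iodine_categories))
  visual <- factor(iodine_categories[which.max(vis_tab)],
                   levels = iodine_categories, ordered = TRUE)

  structure(
    list(transform = tr, readings = readings, calibration = curve,
         zones = zones,
         estimate = pooled$pooled_estimate,
         flags = list(
           below_range_negative = pooled$below_range_negative,
           above_range_extrapolated = pooled$above_range_extrapolated,
           calibration_degenerate = curve$degenerate),
         category = categorize(pooled$pooled_estimate),
         visual_category = visual),
    class = "card_result")
}

# pool any number of sample zones (pool_replicates() proper is capped at the
# three circles of one row)
pool_replicates_any <- function(q, method) {
  pooled <- if (method == "mean") mean(q$estimate) else median(q$estimate)
  data.frame(pooled_estimate = pooled,
             below_range_negative = pooled < 0 || any(q$below_range_negative),
             above_range_extrapolated = pooled > 300 ||
               any(q$above_range_extrapolated))
}

#' @export
print.card_result <- function(x, ...) {
  cat(sprintf("<card_result> estimate %.1f ug I/L (%s; visual read %s)\n",
              x$estimate, as.character(x$category),
              as.character(x$visual_category)))
  if (x$flags$below_range_negative) cat("  flag: below-range (negative)\n")
  if (x$flags$above_range_extrapolated) cat("  flag: above-range (extrapolated)\n")
  invisible(x)
}

#' Analyze a whole validation study
#'
#' Runs [analyze_card()] over every card of a study (as produced by
#' [generate_validation_study()], or any manifest plus images) and returns a
#' tidy per-card results table.
#'
#' @param study A list with elements `images` (named list of `card_image`s
#'   keyed by `card_id`, or `NULL` to read from `manifest$image_path`) and
#'   `manifest` (data frame with `card_id`, `analyst_id`, `solution_id`,
#'   `true_conc`, optionally `image_path`).
#' @param layout The `card_layout`.
#' @param ... Passed to [analyze_card()].
#' @return Data frame with one row per card: ids, `true_conc`,
#'   `true_category`, `estimate`, range flags, `category`,
#'   `visual_category`, calibration `slope`, `intercept`, `r_squared`.
#' @export
analyze_study <- function(study, layout = default_card_layout(), ...) {
  man <- study$manifest
  rows <- lapply(seq_len(nrow(man)), function(i) {
    img <- if (!is.null(study$images)) {
      study$images[[man$card_id[i]]]
    } else {
      man$image_path[i]
    }
    res <- analyze_card(img, layout, ...)
    data.frame(card_id = man$card_id[i], analyst_id = man$analyst_id[i],
               solution_id = man$solution_id[i], true_conc = man$true_conc[i],
               estimate = res$estimate,
               below_range_negative = res$flags$below_range_negative,
               above_range_extrapolated = res$flags$above_range_extrapolated,
               category = as.character(res$category),
               visual_category = as.character(res$visual_category),
               slope = res$calibration$slope,
               intercept = res$calibration$intercept,
               r_squared = res$calibration$r_squared)
  })
  out <- do.call(rbind, rows)
  out$true_category <- as.character(categorize(out$true_conc))
  out[, c("card_id", "analyst_id", "solution_id", "true_conc",
          "true_category", "estimate", "below_range_negative",
          "above_range_extrapolated", "category", "visual_category",
          "slope", "intercept", "r_squared")]
}
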