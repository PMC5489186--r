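#' Simulated visual read of a sample zone
#'
#' Emulates a human reading the card by eye: the sample zone's colour is
#' compared with the three internal standards and assigned the category of
#' the nearest standard (Euclidean distance in raw sRGB). Nearest to the
#' 0 ug I/L standard reads deficient, to the 100 standard adequate, to the
#' 300 standard excessive; exact ties break toward the lower category,
#' the conservative direction for a screening assay.
#'
#' @param sample_reading Numeric RGB triple, or a one-row zone-reading data
#'   frame (with `mean_r`, `mean_g`, `mean_b`).
#' @param standard_readings 3 x 3 matrix of standard RGB rows in
#'   concentration order (0, 100, 300), or the three standard rows of an
#'   [extract_zone_stats()] data frame (ordered by `standard_conc`).
#' @return An `iodine_categories` factor level.
#' @export
simulated_visual_read <- function(sample_reading, standard_readings) {
  as_rgb <- function(x) {
    if (is.data.frame(x)) {
      as.matrix(x[, c("mean_r", "mean_g", "mean_b")])
    } else {
      matrix(x, ncol = 3)
    }
  }
  smp <- as_rgb(sample_reading)
  std <- as_rgb(standard_readings)
  if (is.data.frame(standard_readings) &&
      "standard_conc" %in% names(standard_readings)) {
    std <- std[order(standard_readings$standard_conc), , drop = FALSE]
  }
  if (nrow(std) != 3L) {
    stop("need the three standard readings in concentration order",
         call. = FALSE)
  }
  if (any(!is.finite(smp)) || any(!is.finite(std))) {
    stop("readings must have finite channel means", call. = FALSE)
  }
  cats <- vapply(seq_len(nrow(smp)), function(i) {
    d <- sqrt(rowSums(sweep(std, 2, smp[i, ])^2))
    which.min(d)  # which.min takes the first (lowest category) on ties
  }, integer(1))
  factor(iodine_categories[cats], levels = iodine_categories, ordered = TRUE)
}
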