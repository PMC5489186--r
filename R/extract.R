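#' Extract per-zone channel statistics from a card image
#'
#' For each of the nine reaction zones, samples the pixels of a disc eroded
#' inward from the wax boundary (by `erosion` times the zone radius, to avoid
#' boundary pixels) and reports the unweighted arithmetic mean of the red,
#' green and blue 8-bit channels together with the red-minus-blue score.
#' Channel values are used as stored (sRGB, no gamma linearisation),
#' mirroring a split-channel mean-intensity measurement. A zone whose disc
#' falls partly outside the image is flagged (`out_of_frame`) rather than
#' failing the whole card; colour-standard patches, when present in the
#' layout, are read and appended with role `"patch"` for diagnostics.
#'
#' @param image A `card_image` (H x W x 3 integer array, 0-255).
#' @param layout The `card_layout`.
#' @param transform A [registration_transform()], typically from
#'   [detect_fiducials()].
#' @param erosion Fraction of the zone radius eroded from the sampling disc.
#' @param read_patches Whether to append colour-patch readings.
#' @return Data frame with columns `zone_id`, `role`, `standard_conc`,
#'   `mean_r`, `mean_g`, `mean_b`, `n_pixels`, `score`, `out_of_frame`.
#' @export
extract_zone_stats <- function(image, layout, transform, erosion = 0.15,
                               read_patches = FALSE) {
  img <- unclass(image)
  H <- dim(img)[1]; W <- dim(img)[2]
  k <- px_per_mm(layout$dpi)
  z <- layout$zones

  centers <- apply_transform(cbind(z$x_mm, z$y_mm) * k, transform)
  radii <- z$radius_mm * (1 - erosion) * k * transform$scale

  one_zone <- function(cx, cy, r) {
    if (cx - r < 0 || cx + r > W - 1 || cy - r < 0 || cy + r > H - 1) {
      return(list(mean = rep(NA_real_, 3), n = 0L, oof = TRUE))
    }
    xr <- floor(cx - r):ceiling(cx + r)
    yr <- floor(cy - r):ceiling(cy + r)
    gx <- rep(xr, each = length(yr))
    gy <- rep(yr, times = length(xr))
    inside <- (gx - cx)^2 + (gy - cy)^2 <= r^2
    gx <- gx[inside]; gy <- gy[inside]
    m <- vapply(1:3, function(i) {
      mean(img[, , i][cbind(gy + 1, gx + 1)])
    }, numeric(1))
    list(mean = m, n = length(gx), oof = FALSE)
  }

  rows <- lapply(seq_len(nrow(z)), function(i) {
    one_zone(centers[i, 1], centers[i, 2], radii[i])
  })
  out <- data.frame(
    zone_id = z$zone_id, role = z$role, standard_conc = z$standard_conc,
    mean_r = vapply(rows, function(r) r$mean[1], numeric(1)),
    mean_g = vapply(rows, function(r) r$mean[2], numeric(1)),
    mean_b = vapply(rows, function(r) r$mean[3], numeric(1)),
    n_pixels = vapply(rows, function(r) r$n, integer(1)),
    out_of_frame = vapply(rows, function(r) r$oof, logical(1)))
  out$score <- out$mean_r - out$mean_b

  if (read_patches && !is.null(layout$color_patches)) {
    p <- layout$color_patches
    pc <- apply_transform(cbind(p$x_mm, p$y_mm) * k, transform)
    pr <- p$half_size_mm * 0.7 * k * transform$scale  # inner square as a disc
    prow <- lapply(seq_len(nrow(p)), function(i) one_zone(pc[i, 1], pc[i, 2], pr[i]))
    pdf <- data.frame(
      zone_id = paste0("patch_", seq_len(nrow(p))), role = "patch",
      standard_conc = NA_real_,
      mean_r = vapply(prow, function(r) r$mean[1], numeric(1)),
      mean_g = vapply(prow, function(r) r$mean[2], numeric(1)),
      mean_b = vapply(prow, function(r) r$mean[3], numeric(1)),
      n_pixels = vapply(prow, function(r) r$n, integer(1)),
      out_of_frame = vapply(prow, function(r) r$oof, logical(1)))
    pdf$score <- pdf$mean_r - pdf$mean_b
    out <- rbind(out, pdf)
  }
  out[, c("zone_id", "role", "standard_conc", "mean_r", "mean_g", "mean_b",
          "n_pixels", "score", "out_of_frame")]
}

#' Red-minus-blue score of a zone reading
#'
#' The card's quantitative colorimetric metric: mean red-channel intensity
#' minus mean blue-channel intensity. Blue-appearing blanks score negative;
#' red-appearing iodide-rich zones score positive. The score is invariant to
#' adding the same offset to all three channels.
#'
#' @param reading A data frame of zone readings (from
#'   [extract_zone_stats()]) or a numeric RGB triple / n x 3 matrix of
#'   channel means.
#' @return Numeric score(s), in 8-bit intensity units (range -255 to 255).
#' @examples
#' rb_score(c(200, 50, 80))  # 120
#' @export
rb_score <- function(reading) {
  if (is.data.frame(reading)) {
    if (any(!is.finite(reading$mean_r) | !is.finite(reading$mean_b))) {
      stop("zone reading has non-finite channel means", call. = FALSE)
    }
    return(reading$mean_r - reading$mean_b)
  }
  m <- if (is.null(dim(reading))) matrix(reading, ncol = 3) else reading
  if (any(!is.finite(m))) {
    stop("zone reading has non-finite channel means", call. = FALSE)
  }
  unname(m[, 1] - m[, 3])
}
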