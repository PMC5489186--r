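#' Build a full zone-to-concentration assignment
#'
#' Expands a sample concentration (scalar, or one value per sample zone) to
#' the named 9-zone assignment [render_card()] expects; the standards row is
#' fixed at 0/100/300 ug I/L.
#'
#' @param sample_conc Concentration(s) for the sample zones (ug I/L); a
#'   scalar is recycled to all six replicates.
#' @param layout A `card_layout`.
#' @return Named numeric vector over all nine zone ids.
#' @export
card_assignments <- function(sample_conc, layout = default_card_layout()) {
  z <- layout$zones
  out <- setNames(numeric(nrow(z)), z$zone_id)
  std <- z$role == "standard"
  out[std] <- z$standard_conc[std]
  ns <- sum(!std)
  if (!length(sample_conc) %in% c(1L, ns)) {
    stop("sample_conc must have length 1 or ", ns, call. = FALSE)
  }
  out[!std] <- rep(sample_conc, length.out = ns)
  out
}

#' Render a synthetic card photograph
#'
#' Draws an 8-bit sRGB image of a card: white paper, dark fiducial discs,
#' colour-standard patches and the nine reaction zones filled with the
#' colour-response model's colours at read time `t`, then applies (in order)
#' per-zone chemical score noise, the similarity transform, the illumination
#' gradient, per-pixel Gaussian noise, clipping to \[0, 255\] and rounding.
#' With zero noise, zero gradient and the identity transform, each zone
#' interior is uniform and equals the (rounded) [sk_color_trajectory()]
#' colour.
#'
#' @param layout A `card_layout`.
#' @param assignments Named numeric vector mapping every zone id to a
#'   concentration (ug I/L); see [card_assignments()]. The standards must be
#'   assigned their nominal 0/100/300 values.
#' @param model A [color_response_model()].
#' @param imaging An [imaging_model()].
#' @param t Read time, minutes.
#' @return A `card_image`: integer array (height x width x 3), 0-255, with
#'   the true transform stored in `attr(, "transform")`.
#' @export
render_card <- function(layout, assignments, model = color_response_model(),
                        imaging = imaging_model(), t = 3) {
  z <- layout$zones
  if (is.null(names(assignments)) || !setequal(names(assignments), z$zone_id) ||
      length(assignments) != nrow(z)) {
    stop("assignments must name every zone exactly once", call. = FALSE)
  }
  std <- z$role == "standard"
  if (!isTRUE(all.equal(unname(assignments[z$zone_id[std]]),
                        z$standard_conc[std]))) {
    stop("standard zones must be assigned their nominal 0/100/300 ug I/L",
         call. = FALSE)
  }
  sz <- canvas_size(layout)
  W <- sz["w"]; H <- sz["h"]
  k <- px_per_mm(layout$dpi)
  tr <- registration_transform(imaging$rotation_deg, imaging$translation_px,
                               imaging$scale,
                               center_px = c((W - 1) / 2, (H - 1) / 2))

  # all drawn elements must land inside the frame
  zc <- apply_transform(cbind(z$x_mm, z$y_mm) * k, tr)
  zr <- z$radius_mm * k * tr$scale
  if (any(zc[, 1] - zr < 0 | zc[, 1] + zr > W - 1 |
          zc[, 2] - zr < 0 | zc[, 2] + zr > H - 1)) {
    stop("transform pushes reaction zones outside the image frame",
         call. = FALSE)
  }

  with_seed(imaging$seed, {
    conc <- assignments[z$zone_id]
    cols <- sk_color_trajectory(unname(conc), t, model)
    if (is.null(dim(cols))) cols <- matrix(cols, nrow = 1)
    if (model$score_noise_sd > 0) {
      e <- rnorm(nrow(z), 0, model$score_noise_sd)
      cols[, 1] <- cols[, 1] + e / 2   # shifts the red-minus-blue score by e
      cols[, 3] <- cols[, 3] - e / 2
    }

    # inverse-map the pixel grid to card-local mm once
    xs <- rep(0:(W - 1), each = H)
    ys <- rep(0:(H - 1), times = W)
    mm <- invert_transform(cbind(xs, ys), tr) / k
    mx <- matrix(mm[, 1], H, W); my <- matrix(mm[, 2], H, W)

    ch <- lapply(1:3, function(i) matrix(255, H, W))
    fill_disc <- function(cx, cy, r, rgb) {
      m <- (mx - cx)^2 + (my - cy)^2 <= r^2
      for (i in 1:3) ch[[i]][m] <<- rgb[i]
    }
    for (i in seq_len(nrow(layout$fiducials))) {
      fill_disc(layout$fiducials[i, 1], layout$fiducials[i, 2],
                layout$fiducial_radius_mm, c(0, 0, 0))
    }
    if (!is.null(layout$color_patches)) {
      p <- layout$color_patches
      for (i in seq_len(nrow(p))) {
        m <- abs(mx - p$x_mm[i]) <= p$half_size_mm[i] &
             abs(my - p$y_mm[i]) <= p$half_size_mm[i]
        for (j in 1:3) ch[[j]][m] <- c(p$r[i], p$g[i], p$b[i])[j]
      }
    }
    for (i in seq_len(nrow(z))) {
      fill_disc(z$x_mm[i], z$y_mm[i], z$radius_mm[i], cols[i, ])
    }

    img <- array(0, dim = c(H, W, 3))
    for (i in 1:3) img[, , i] <- ch[[i]]
    if (imaging$illumination_gradient != 0) {
      f <- 1 + imaging$illumination_gradient * ((0:(W - 1)) / (W - 1) - 0.5)
      img <- sweep(img, 2, f, "*")
    }
    if (imaging$pixel_noise_sd > 0) {
      img <- img + rnorm(length(img), 0, imaging$pixel_noise_sd)
    }
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    structure(img, class = "card_image", transform = tr, dpi = layout$dpi)
  })
}

#' Read / write card images as 8-bit PNG (or TIFF)
#'
#' @param path File path; `.png` always supported, `.tif`/`.tiff` if the
#'   tiff package is installed.
#' @return `read_card_image`: a `card_image` integer array (H x W x 3).
#' @export
read_card_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the tiff package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3))
  img <- round(arr[, , 1:3, drop = FALSE] * 255)
  storage.mode(img) <- "integer"
  structure(img, class = "card_image")
}

#' @rdname read_card_image
#' @param image A `card_image` or compatible H x W x 3 array (0-255).
#' @export
write_card_image <- function(image, path) {
  arr <- unclass(image) / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' @export
print.card_image <- function(x, ...) {
  d <- dim(x)
  cat("<card_image> ", d[2], "x", d[1], " px, 3 channels (8-bit)\n", sep = "")
  invisible(x)
}

#' @export
plot.card_image <- function(x, ...) {
  plot(NULL, xlim = c(0, dim(x)[2]), ylim = c(dim(x)[1], 0), asp = 1,
       xlab = "x (px)", ylab = "y (px)", ...)
  rasterImage(as.raster(unclass(x) / 255), 0, dim(x)[1], dim(x)[2], 0)
}
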