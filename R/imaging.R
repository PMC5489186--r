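#' Imaging model for synthetic card photographs
#'
#' Captures the nuisance variation a light-box phone photograph introduces:
#' i.i.d. Gaussian pixel noise per channel, a linear multiplicative
#' illumination gradient across the card, and a similarity misalignment
#' (rotation about the image centre, translation, isotropic scale). With a
#' fixed seed the rendered image is bit-reproducible.
#'
#' @param pixel_noise_sd Per-pixel, per-channel noise standard deviation in
#'   8-bit intensity units (>= 0).
#' @param illumination_gradient Maximal fractional brightness change across
#'   the card width (0 disables the gradient).
#' @param rotation_deg Rotation of the card in the frame, degrees.
#' @param translation_px Length-2 translation in pixels.
#' @param scale Isotropic scale factor (> 0).
#' @param seed Integer seed for the renderer's random draws, or `NULL` to
#'   use the current RNG state.
#' @return An object of class `imaging_model`.
#' @export
imaging_model <- function(pixel_noise_sd = 2, illumination_gradient = 0,
                          rotation_deg = 0, translation_px = c(0, 0),
                          scale = 1, seed = NULL) {
  stopifnot(pixel_noise_sd >= 0, scale > 0, length(translation_px) == 2)
  structure(list(pixel_noise_sd = pixel_noise_sd,
                 illumination_gradient = illumination_gradient,
                 rotation_deg = rotation_deg,
                 translation_px = as.numeric(translation_px),
                 scale = scale,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "imaging_model")
}

# evaluate a function under a temporary seed, restoring the RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# similarity transform helpers -------------------------------------------

# px-per-mm conversion factor
px_per_mm <- function(dpi) dpi / 25.4

canvas_size <- function(layout) {
  k <- px_per_mm(layout$dpi)
  c(w = ceiling(layout$card_size_mm[1] * k),
    h = ceiling(layout$card_size_mm[2] * k))
}

#' Similarity registration transform
#'
#' Rotation (degrees, about the image centre), translation (px), isotropic
#' scale, and the RMS fiducial residual of the fit that produced it.
#' Maps card-layout pixel coordinates (layout mm times dpi/25.4, origin
#' top-left, x rightward, y downward, pixel centres at integer coordinates)
#' to image pixel coordinates.
#'
#' @param rotation_deg,translation_px,scale Transform parameters.
#' @param center_px Length-2 centre of rotation in pixels.
#' @param residual_px RMS residual over fiducials (0 for an exact/injected
#'   transform).
#' @return An object of class `registration_transform`.
#' @export
registration_transform <- function(rotation_deg = 0, translation_px = c(0, 0),
                                   scale = 1, center_px = c(0, 0),
                                   residual_px = 0) {
  stopifnot(scale > 0, residual_px >= 0)
  structure(list(rotation_deg = rotation_deg,
                 translation_px = as.numeric(translation_px),
                 scale = scale, center_px = as.numeric(center_px),
                 residual_px = residual_px),
            class = "registration_transform")
}

#' @export
print.registration_transform <- function(x, ...) {
  cat(sprintf(
    "<registration_transform> rot %.3f deg, shift (%.2f, %.2f) px, scale %.4f, residual %.3f px\n",
    x$rotation_deg, x$translation_px[1], x$translation_px[2], x$scale,
    x$residual_px))
  invisible(x)
}

rotation_matrix <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# forward map: layout px coords (n x 2) -> image px coords
apply_transform <- function(pts, tr) {
  pts <- matrix(pts, ncol = 2)
  ctr <- matrix(tr$center_px, nrow(pts), 2, byrow = TRUE)
  off <- matrix(tr$translation_px, nrow(pts), 2, byrow = TRUE)
  (pts - ctr) %*% t(rotation_matrix(tr$rotation_deg)) * tr$scale + ctr + off
}

# inverse map: image px coords -> layout px coords
invert_transform <- function(pts, tr) {
  pts <- matrix(pts, ncol = 2)
  ctr <- matrix(tr$center_px, nrow(pts), 2, byrow = TRUE)
  off <- matrix(tr$translation_px, nrow(pts), 2, byrow = TRUE)
  ((pts - ctr - off) / tr$scale) %*% rotation_matrix(tr$rotation_deg) + ctr
}
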