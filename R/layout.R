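#' Card layout description
#'
#' A `card_layout` records the geometry of a test card in card-local
#' millimetres: fiducial registration marks, the nine reaction zones (top row
#' = internal standards at 0, 100 and 300 ug I/L; rows two and three = sample
#' replicates), and printed colour-standard patches. The layout drives both
#' the synthetic renderer and zone extraction from photographs.
#'
#' @param card_size_mm Numeric length-2, card width and height in mm.
#' @param dpi Rendering / nominal imaging resolution in dots per inch.
#' @param fiducials Matrix (n x 2) of fiducial centre positions in mm.
#'   At least two are required for a similarity registration fit.
#' @param fiducial_radius_mm Radius of the printed fiducial discs.
#' @param zones Data frame with columns `zone_id`, `role`
#'   (`"standard"`/`"sample"`), `standard_conc` (ug I/L, `NA` for samples),
#'   `x_mm`, `y_mm`, `radius_mm`. Exactly nine rows; the standards must carry
#'   concentrations 0, 100 and 300.
#' @param color_patches Data frame with columns `x_mm`, `y_mm`,
#'   `half_size_mm`, `r`, `g`, `b` describing printed reference patches
#'   (read and reported, not used for correction by default).
#' @return An object of class `card_layout`.
#' @seealso [default_card_layout()], [load_layout()]
#' @export
card_layout <- function(card_size_mm, dpi, fiducials, fiducial_radius_mm,
                        zones, color_patches = NULL) {
  layout <- structure(
    list(card_size_mm = as.numeric(card_size_mm),
         dpi = as.numeric(dpi),
         fiducials = as.matrix(fiducials),
         fiducial_radius_mm = as.numeric(fiducial_radius_mm),
         zones = as.data.frame(zones),
         color_patches = if (is.null(color_patches)) NULL
                         else as.data.frame(color_patches)),
    class = "card_layout")
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  z <- layout$zones
  if (nrow(z) != 9L) {
    stop("layout must define exactly 9 reaction zones, got ", nrow(z),
         call. = FALSE)
  }
  need <- c("zone_id", "role", "standard_conc", "x_mm", "y_mm", "radius_mm")
  if (!all(need %in% names(z))) {
    stop("zone table is missing columns: ",
         paste(setdiff(need, names(z)), collapse = ", "), call. = FALSE)
  }
  std <- z[z$role == "standard", ]
  if (nrow(std) != 3L || !identical(sort(std$standard_conc), c(0, 100, 300))) {
    stop("layout must carry standards at exactly 0, 100 and 300 ug I/L",
         call. = FALSE)
  }
  if (length(layout$card_size_mm) != 2L || any(layout$card_size_mm <= 0)) {
    stop("card_size_mm must be two positive numbers", call. = FALSE)
  }
  if (layout$dpi <= 0) stop("dpi must be positive", call. = FALSE)
  if (ncol(layout$fiducials) != 2L || nrow(layout$fiducials) < 2L) {
    stop("at least two fiducials (x, y) are required", call. = FALSE)
  }
  # zones must be pairwise disjoint discs inside the card bounds
  w <- layout$card_size_mm[1]; h <- layout$card_size_mm[2]
  if (any(z$x_mm - z$radius_mm < 0 | z$x_mm + z$radius_mm > w |
          z$y_mm - z$radius_mm < 0 | z$y_mm + z$radius_mm > h)) {
    stop("all reaction zones must lie inside the card bounds", call. = FALSE)
  }
  d <- as.matrix(dist(z[, c("x_mm", "y_mm")]))
  rr <- outer(z$radius_mm, z$radius_mm, "+")
  diag(d) <- Inf
  if (any(d <= rr)) {
    stop("reaction zones must be disjoint discs (overlap detected)",
         call. = FALSE)
  }
  invisible(layout)
}

#' Default card layout
#'
#' Ships the 3x3 card arrangement: standards (0, 100, 300 ug I/L) in the top
#' row, six sample replicate zones in rows two and three, four asymmetric
#' corner fiducials and three grey colour-standard patches, on a 60 x 72 mm
#' card rendered at 150 dpi.
#'
#' @param dpi Imaging resolution; lower values render faster.
#' @return A `card_layout`.
#' @export
default_card_layout <- function(dpi = 150) {
  zones <- data.frame(
    zone_id = c("std_0", "std_100", "std_300", paste0("sample_", 1:6)),
    role = c(rep("standard", 3), rep("sample", 6)),
    standard_conc = c(0, 100, 300, rep(NA_real_, 6)),
    x_mm = rep(c(15, 30, 45), 3),
    y_mm = rep(c(20, 32, 44), each = 3),
    radius_mm = 5)
  patches <- data.frame(
    x_mm = c(22, 30, 38), y_mm = 67, half_size_mm = 2.5,
    r = c(220, 160, 100), g = c(220, 160, 100), b = c(220, 160, 100))
  card_layout(
    card_size_mm = c(60, 72), dpi = dpi,
    fiducials = rbind(c(6, 6), c(54, 6), c(6, 64), c(52, 58)),
    fiducial_radius_mm = 1.6,
    zones = zones, color_patches = patches)
}

#' Load a card layout from a JSON document
#'
#' Reads a layout configuration (see Details) and validates it: exactly nine
#' zones, standards at 0/100/300 ug I/L, disjoint discs inside the card.
#' Omitted optional fields receive the defaults of [default_card_layout()].
#'
#' @details The JSON schema has keys `card_size_mm` (`[w, h]`), `dpi`,
#'   `fiducials` (list of `[x_mm, y_mm]`), `fiducial_radius_mm`, `zones`
#'   (list of objects with `zone_id`, `center` `[x, y]`, `radius`, `role`,
#'   and `standard_conc` for standards) and optional `color_patches` (objects
#'   with `center`, `half_size`, `rgb`).
#'
#' @param path Path to a JSON file, or a JSON string.
#' @return A validated `card_layout`.
#' @export
load_layout <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  def <- default_card_layout()
  get_or <- function(key, default) if (is.null(doc[[key]])) default else doc[[key]]
  if (is.null(doc$zones)) stop("layout config has no `zones` key", call. = FALSE)
  zones <- do.call(rbind, lapply(doc$zones, function(zn) {
    if (is.null(zn$center) || length(zn$center) != 2L) {
      stop("each zone needs a `center` of two coordinates", call. = FALSE)
    }
    data.frame(zone_id = if (is.null(zn$zone_id)) NA_character_ else zn$zone_id,
               role = if (is.null(zn$role)) "sample" else zn$role,
               standard_conc = if (is.null(zn$standard_conc)) NA_real_
                               else as.numeric(zn$standard_conc),
               x_mm = zn$center[1], y_mm = zn$center[2],
               radius_mm = if (is.null(zn$radius)) 5 else as.numeric(zn$radius))
  }))
  if (any(is.na(zones$zone_id))) {
    zones$zone_id <- ifelse(is.na(zones$zone_id),
                            paste0("zone_", seq_len(nrow(zones))),
                            zones$zone_id)
  }
  patches <- NULL
  if (!is.null(doc$color_patches)) {
    patches <- do.call(rbind, lapply(doc$color_patches, function(p) {
      data.frame(x_mm = p$center[1], y_mm = p$center[2],
                 half_size_mm = if (is.null(p$half_size)) 2.5
                                else as.numeric(p$half_size),
                 r = p$rgb[1], g = p$rgb[2], b = p$rgb[3])
    }))
  }
  fid <- get_or("fiducials", NULL)
  if (is.list(fid)) fid <- do.call(rbind, fid)
  card_layout(
    card_size_mm = get_or("card_size_mm", def$card_size_mm),
    dpi = get_or("dpi", def$dpi),
    fiducials = if (is.null(fid)) def$fiducials else fid,
    fiducial_radius_mm = get_or("fiducial_radius_mm", def$fiducial_radius_mm),
    zones = zones, color_patches = patches)
}

#' Serialize a card layout to JSON
#'
#' Inverse of [load_layout()]: `load_layout(write_layout(layout))` returns an
#' identical layout.
#'
#' @param layout A `card_layout`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_layout <- function(layout, path = NULL) {
  stopifnot(inherits(layout, "card_layout"))
  z <- layout$zones
  doc <- list(
    card_size_mm = layout$card_size_mm,
    dpi = layout$dpi,
    fiducials = lapply(seq_len(nrow(layout$fiducials)),
                       function(i) unname(layout$fiducials[i, ])),
    fiducial_radius_mm = layout$fiducial_radius_mm,
    zones = lapply(seq_len(nrow(z)), function(i) {
      zn <- list(zone_id = z$zone_id[i], role = z$role[i],
                 center = c(z$x_mm[i], z$y_mm[i]), radius = z$radius_mm[i])
      if (!is.na(z$standard_conc[i])) zn$standard_conc <- z$standard_conc[i]
      zn
    }))
  if (!is.null(layout$color_patches)) {
    p <- layout$color_patches
    doc$color_patches <- lapply(seq_len(nrow(p)), function(i) {
      list(center = c(p$x_mm[i], p$y_mm[i]), half_size = p$half_size_mm[i],
           rgb = c(p$r[i], p$g[i], p$b[i]))
    })
  }
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.card_layout <- function(x, ...) {
  cat("<card_layout> ", x$card_size_mm[1], "x", x$card_size_mm[2], "mm at ",
      x$dpi, " dpi\n", sep = "")
  cat("  fiducials:", nrow(x$fiducials), " zones:", nrow(x$zones),
      " (standards 0/100/300 ug I/L)\n")
  invisible(x)
}
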