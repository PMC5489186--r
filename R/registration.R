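#' Detect fiducials and fit the card registration transform
#'
#' Finds the printed dark fiducial discs in a card photograph, groups dark
#' pixels into blobs (single-linkage clustering, equivalent to connected
#' components for well-separated marks), takes blob centroids, and fits the
#' similarity transform (rotation, translation, isotropic scale) that best
#' maps the layout's fiducial positions onto the detected centroids in the
#' least-squares sense. Correspondence is resolved by trying every
#' permutation of the detected points and keeping the fit with the smallest
#' RMS residual, which is robust because the default fiducial arrangement is
#' asymmetric.
#'
#' @param image A `card_image` (or H x W x 3 array, 0-255).
#' @param layout The `card_layout` the card was printed from.
#' @param dark_threshold Maximum channel intensity for a pixel to count as
#'   fiducial ink.
#' @param min_blob_px Blobs smaller than this are discarded as specks.
#' @return A [registration_transform()] with the RMS fiducial residual.
#' @export
detect_fiducials <- function(image, layout, dark_threshold = 80,
                             min_blob_px = 20) {
  img <- unclass(image)
  H <- dim(img)[1]; W <- dim(img)[2]
  dark <- img[, , 1] < dark_threshold & img[, , 2] < dark_threshold &
          img[, , 3] < dark_threshold
  idx <- which(dark, arr.ind = TRUE)
  n_fid <- nrow(layout$fiducials)
  if (nrow(idx) < n_fid * min_blob_px) {
    stop("registration failure: card fiducials not found in image",
         call. = FALSE)
  }
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)  # 0-based pixel centres

  # cluster dark pixels into blobs; subsample first if there are many
  sub <- pts
  if (nrow(sub) > 3000L) {
    sub <- sub[unique(round(seq(1, nrow(sub), length.out = 3000L))), ]
  }
  cl <- cutree(hclust(dist(sub), method = "single"), h = 5)
  centers <- do.call(rbind, lapply(split(seq_len(nrow(sub)), cl),
                                   function(i) colMeans(sub[i, , drop = FALSE])))
  # assign every dark pixel to its nearest blob and recompute centroids
  d2 <- outer(pts[, 1], centers[, 1], "-")^2 + outer(pts[, 2], centers[, 2], "-")^2
  lab <- max.col(-d2)
  sizes <- tabulate(lab, nbins = nrow(centers))
  keep <- which(sizes >= min_blob_px)
  if (length(keep) < n_fid) {
    stop("registration failure: found ", length(keep), " fiducial blobs, need ",
         n_fid, call. = FALSE)
  }
  keep <- keep[order(sizes[keep], decreasing = TRUE)][seq_len(n_fid)]
  obs <- do.call(rbind, lapply(keep, function(l) {
    colMeans(pts[lab == l, , drop = FALSE])
  }))

  k <- px_per_mm(layout$dpi)
  ref <- layout$fiducials * k
  sz <- canvas_size(layout)
  ctr <- c((sz["w"] - 1) / 2, (sz["h"] - 1) / 2)

  # resolve correspondence: best similarity fit over permutations
  perms <- permutations(n_fid)
  best <- NULL
  for (p in seq_len(nrow(perms))) {
    fit <- fit_similarity(ref, obs[perms[p, ], , drop = FALSE])
    if (is.null(best) || fit$rms < best$rms) best <- fit
  }

  # express as rotation about the canvas centre plus translation
  ctr_mapped <- best$s * (rotation_matrix_from(best$R) %*% ctr) + best$d
  registration_transform(
    rotation_deg = atan2(best$R[2, 1], best$R[1, 1]) * 180 / pi,
    translation_px = as.numeric(ctr_mapped - ctr),
    scale = best$s,
    center_px = as.numeric(ctr),
    residual_px = best$rms)
}

rotation_matrix_from <- function(R) R

# least-squares similarity (Umeyama): obs ~ s * R %*% ref + d
fit_similarity <- function(ref, obs) {
  mx <- colMeans(ref); my <- colMeans(obs)
  X <- sweep(ref, 2, mx); Y <- sweep(obs, 2, my)
  S <- t(Y) %*% X / nrow(ref)
  sv <- svd(S)
  D <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% D %*% t(sv$v)
  varX <- sum(X^2) / nrow(ref)
  s <- sum(diag(D %*% diag(sv$d))) / varX
  d <- my - s * as.numeric(R %*% mx)
  pred <- t(s * R %*% t(ref) + d)
  rms <- sqrt(mean(rowSums((obs - pred)^2)))
  list(R = R, s = s, d = d, rms = rms)
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n))[-i][sub], nrow(sub)))
  }))
}
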