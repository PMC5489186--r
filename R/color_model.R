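#' Empirical colour-response model for the Sandell-Kolthoff card
#'
#' The card's ferroin/ferriin readout moves from blue (no iodide: excess
#' Ce(IV) keeps the indicator oxidised) through purple to red (iodide-rich:
#' the reaction completes and arsenite regenerates ferroin) as iodide
#' concentration increases. No rate constants are available for the reaction
#' as run on paper, so the generator is an empirical interpolation: the zone
#' colour at the reference read time (3 min) is a monotone piecewise-cubic
#' interpolation per channel through three anchor colours at 0, 100 and
#' 300 ug I/L, with an exponential saturating tail above 300 (scores plateau
#' outside the 50-300 ug I/L sensitivity window). A time factor scales colour
#' separation from the blank: small before ~2 min, 1 at the 3 min read, and
#' mildly saturating beyond, reproducing the observation that standards are
#' best distinguished 3-5 minutes into the reaction.
#'
#' @param anchor_blank,anchor_adequate,anchor_excessive RGB triples (0-255)
#'   for the 0, 100 and 300 ug I/L standards at the reference read time.
#'   Defaults: blue-ish, purple-ish, red-ish.
#' @param response `"saturating"` (default: monotone cubic through all three
#'   anchors, logistic-style tail above 300) or `"linear"` (channel values
#'   exactly linear in concentration between the blank and excessive anchors
#'   over all concentrations; the 100 anchor is replaced by the collinear
#'   point). The linear option gives a score exactly linear in concentration,
#'   which makes calibration inversion exact.
#' @param sensitivity_range Concentration window (ug I/L) of maximal colour
#'   sensitivity; outside it the response saturates.
#' @param tail_fraction Fraction of the (excessive - adequate) channel step
#'   still available asymptotically above 300 ug I/L.
#' @param tail_scale_ug_l e-folding scale (ug I/L) of the saturating tail.
#' @param time_rate Rate constant (1/min) of the colour-development time
#'   factor `g(t) = (1 - exp(-time_rate * t)) / (1 - exp(-3 * time_rate))`,
#'   normalised so g(3 min) = 1.
#' @param score_noise_sd Standard deviation of zone-level chemical noise on
#'   the red-minus-blue score (score units); applied by [render_card()].
#' @return An object of class `color_response_model`.
#' @seealso [sk_color_trajectory()], [sk_score()]
#' @export
color_response_model <- function(anchor_blank = c(60, 70, 190),
                                 anchor_adequate = c(150, 70, 150),
                                 anchor_excessive = c(190, 70, 60),
                                 response = c("saturating", "linear"),
                                 sensitivity_range = c(50, 300),
                                 tail_fraction = 0.25,
                                 tail_scale_ug_l = 150,
                                 time_rate = 0.8,
                                 score_noise_sd = 6) {
  response <- match.arg(response)
  stopifnot(length(anchor_blank) == 3, length(anchor_adequate) == 3,
            length(anchor_excessive) == 3,
            score_noise_sd >= 0, time_rate > 0, tail_scale_ug_l > 0)
  anchors <- rbind(blank = anchor_blank, adequate = anchor_adequate,
                   excessive = anchor_excessive)
  colnames(anchors) <- c("r", "g", "b")
  if (response == "linear") {
    anchors["adequate", ] <- anchor_blank + (100 / 300) *
      (anchor_excessive - anchor_blank)
  }
  structure(list(anchors = anchors, anchor_conc = c(0, 100, 300),
                 response = response,
                 sensitivity_range = sensitivity_range,
                 tail_fraction = tail_fraction,
                 tail_scale_ug_l = tail_scale_ug_l,
                 time_rate = time_rate,
                 score_noise_sd = score_noise_sd),
            class = "color_response_model")
}

# per-channel colour at the reference read time (t = 3 min), unclipped
reference_color <- function(conc, model) {
  a <- model$anchors
  if (model$response == "linear") {
    sapply(c("r", "g", "b"), function(ch) {
      a["blank", ch] + (conc / 300) * (a["excessive", ch] - a["blank", ch])
    })
  } else {
    inside <- pmin(conc, 300)
    out <- sapply(c("r", "g", "b"), function(ch) {
      y <- a[, ch]
      v <- if (length(unique(y)) == 1L) {
        rep(y[1], length(inside))
      } else {
        # monotone (Hyman-filtered) cubic through the three anchors
        splinefun(model$anchor_conc, y, method = "hyman")(inside)
      }
      tail_amp <- model$tail_fraction * (y[3] - y[2])
      over <- conc > 300
      v[over] <- y[3] + tail_amp *
        (1 - exp(-(conc[over] - 300) / model$tail_scale_ug_l))
      v
    })
    out
  }
}

#' Zone colour as a function of concentration and reaction time
#'
#' Deterministic RGB colour of a reaction zone under a
#' [color_response_model()]. At the reference read time of 3 minutes the
#' blank returns its anchor colour exactly and the implied red-minus-blue
#' score is strictly increasing in concentration across the sensitivity
#' window. Colour separation from the blank grows with time as
#' `g(t)` (normalised to 1 at 3 min), so early reads (t <= 1 min) show
#' compressed score differences.
#'
#' @param conc Concentration(s), ug I/L (>= 0).
#' @param t Reaction time in minutes (> 0).
#' @param model A [color_response_model()].
#' @return Numeric RGB triple (or `length(conc)` x 3 matrix), unclipped
#'   0-255 scale.
#' @examples
#' m <- color_response_model()
#' sk_color_trajectory(0, 3, m)    # the blank anchor
#' sk_color_trajectory(300, 3, m)  # the red 300 ug I/L anchor
#' @export
sk_color_trajectory <- function(conc, t = 3, model = color_response_model()) {
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentration must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(t) || t <= 0) {
    stop("reaction time must be positive", call. = FALSE)
  }
  ref <- reference_color(conc, model)
  if (is.null(dim(ref))) ref <- matrix(ref, nrow = length(conc))
  blank <- reference_color(0, model)
  g <- (1 - exp(-model$time_rate * t)) / (1 - exp(-3 * model$time_rate))
  out <- sweep(sweep(ref, 2, blank, "-") * g, 2, blank, "+")
  colnames(out) <- c("r", "g", "b")
  if (length(conc) == 1L) drop(out) else out
}

#' Red-minus-blue score implied by the colour model
#'
#' Convenience wrapper: the mean-red minus mean-blue score a noiseless zone
#' at concentration `conc` would produce at read time `t`.
#'
#' @inheritParams sk_color_trajectory
#' @return Numeric score(s).
#' @export
sk_score <- function(conc, t = 3, model = color_response_model()) {
  col <- sk_color_trajectory(conc, t, model)
  if (is.null(dim(col))) unname(col["r"] - col["b"]) else col[, "r"] - col[, "b"]
}
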