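#' Generate a synthetic blind validation study
#'
#' Emulates a blind card-validation exercise: `n_solutions` artificial-urine
#' iodide solutions spanning `conc_range` are each run once by every analyst
#' on their own card, and each card image is rendered from the
#' colour-response and imaging models. Concentrations follow a uniform grid
#' over the range with seeded jitter (the grid keeps coverage of all three
#' WHO categories; jitter avoids lattice artefacts). All randomness —
#' concentration jitter, per-zone chemical noise, per-pixel noise — derives
#' from the single `seed`, so identical seeds give identical studies.
#'
#' @param n_solutions Number of coded solutions (default 30).
#' @param conc_range Concentration span in ug I/L (default 0-500, which
#'   places samples above the 300 ug I/L calibration ceiling as a validation
#'   set should).
#' @param n_analysts Number of analysts running each solution (default 2).
#' @param layout The `card_layout`.
#' @param model A [color_response_model()].
#' @param imaging An [imaging_model()]; its `seed` is overridden per card.
#' @param t Read time, minutes.
#' @param seed Integer seed for the whole study.
#' @param dir Optional directory; when given, card PNGs and a
#'   `manifest.csv` are written there and `image_path` is filled in.
#' @return A list of class `validation_study` with `images` (named list of
#'   `card_image`s), `manifest` (one row per card: `card_id`, `analyst_id`,
#'   `solution_id`, `true_conc`, `image_path`) and `params`.
#' @export
generate_validation_study <- function(n_solutions = 30,
                                      conc_range = c(0, 500),
                                      n_analysts = 2,
                                      layout = default_card_layout(),
                                      model = color_response_model(),
                                      imaging = imaging_model(),
                                      t = 3, seed = 1, dir = NULL) {
  if (n_solutions < 1 || n_analysts < 1) {
    stop("n_solutions and n_analysts must be positive", call. = FALSE)
  }
  if (conc_range[1] >= conc_range[2]) {
    stop("conc_range must be increasing", call. = FALSE)
  }
  plan <- with_seed(seed, {
    concs <- study_concentrations(n_solutions, conc_range[1], conc_range[2])
    card_seeds <- sample.int(.Machine$integer.max - 1L,
                             n_solutions * n_analysts)
    list(concs = concs, card_seeds = card_seeds)
  })

  manifest <- expand.grid(solution_id = seq_len(n_solutions),
                          analyst_id = seq_len(n_analysts))
  manifest <- manifest[order(manifest$analyst_id, manifest$solution_id), ]
  manifest$true_conc <- plan$concs[manifest$solution_id]
  manifest$card_id <- sprintf("card_a%d_s%02d", manifest$analyst_id,
                              manifest$solution_id)
  manifest$image_path <- NA_character_
  rownames(manifest) <- NULL

  images <- vector("list", nrow(manifest))
  names(images) <- manifest$card_id
  for (i in seq_len(nrow(manifest))) {
    im <- imaging
    im$seed <- plan$card_seeds[i]
    images[[i]] <- render_card(
      layout, card_assignments(manifest$true_conc[i], layout),
      model = model, imaging = im, t = t)
  }

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(nrow(manifest))) {
      p <- file.path(dir, paste0(manifest$card_id[i], ".png"))
      write_card_image(images[[i]], p)
      manifest$image_path[i] <- p
    }
    write.csv(manifest[, c("card_id", "analyst_id", "solution_id",
                           "true_conc", "image_path")],
              file.path(dir, "manifest.csv"), row.names = FALSE)
  }

  structure(list(images = images,
                 manifest = manifest[, c("card_id", "analyst_id",
                                         "solution_id", "true_conc",
                                         "image_path")],
                 params = list(n_solutions = n_solutions,
                               conc_range = conc_range,
                               n_analysts = n_analysts, t = t, seed = seed)),
            class = "validation_study")
}

# uniform grid over [lo, hi] with jitter of half a grid step, clamped
study_concentrations <- function(n, lo, hi) {
  if (n == 1L) return((lo + hi) / 2)
  grid <- seq(lo, hi, length.out = n)
  step <- (hi - lo) / (n - 1)
  pmin(pmax(grid + runif(n, -step / 2, step / 2), lo), hi)
}

#' @export
print.validation_study <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<validation_study> %d solutions x %d analysts over %g-%g ug I/L (%d cards)\n",
    p$n_solutions, p$n_analysts, p$conc_range[1], p$conc_range[2],
    nrow(x$manifest)))
  invisible(x)
}

#' Predict study error by direct propagation of score noise
#'
#' Score-space Monte Carlo companion to the image pipeline: for each
#' replicate study the configured zone-score noise is added directly to the
#' model's score curve for the standards and the six sample replicates, the
#' same calibration fit and inversion are applied, and the in-range mean
#' absolute error (MAE) against truth is recorded. This propagates the
#' configured score noise through the calibration slope — including the
#' curvature of the saturating response, which biases mid-range estimates —
#' without rendering any images, and so predicts what the imaging pipeline
#' should measure (per-pixel noise averages out over a zone's ~2000 pixels
#' and contributes negligibly to the zone score).
#'
#' @param model A [color_response_model()] (its `score_noise_sd` is the
#'   propagated noise).
#' @param concs True concentrations of the study's cards (one entry per
#'   card).
#' @param n_rep Number of Monte-Carlo study replicates.
#' @param t Read time, minutes.
#' @param seed Integer seed.
#' @param pool Replicate pooling rule.
#' @return A list: `mae_mean`, `mae_sd` (between-study Monte-Carlo SD),
#'   `bias_mean`, `mae_reps` and `bias_reps` (per-replicate values), `n_rep`.
#' @export
predict_study_error <- function(model, concs, n_rep = 200, t = 3, seed = 1,
                                pool = c("mean", "median")) {
  pool <- match.arg(pool)
  std_scores <- sk_score(c(0, 100, 300), t, model)
  true_scores <- sk_score(concs, t, model)
  with_seed(seed, {
    stats <- vapply(seq_len(n_rep), function(r) {
      errs <- unlist(lapply(seq_along(concs), function(i) {
        s_std <- std_scores + rnorm(3, 0, model$score_noise_sd)
        curve <- fit_calibration(c(0, 100, 300), s_std)
        if (curve$degenerate) return(numeric(0))
        s_smp <- true_scores[i] + rnorm(6, 0, model$score_noise_sd)
        q <- quantify(s_smp, curve)
        pooled <- pool_replicates_any(q, pool)
        if (pooled$below_range_negative || pooled$above_range_extrapolated) {
          return(numeric(0))
        }
        pooled$pooled_estimate - concs[i]
      }))
      c(mae = mean(abs(errs)), bias = mean(errs))
    }, numeric(2))
    list(mae_mean = mean(stats["mae", ]), mae_sd = sd(stats["mae", ]),
         bias_mean = mean(stats["bias", ]), mae_reps = stats["mae", ],
         bias_reps = stats["bias", ], n_rep = n_rep)
  })
}
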