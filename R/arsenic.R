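# atomic mass of arsenic, g/mol; As2O3 carries two As per formula unit
AS_ATOMIC_MASS <- 74.9216

#' Arsenic mass delivered to one reaction circle
#'
#' Each circle receives a fixed volume of As2O3 solution; the arsenic mass
#' is volume x molarity x 2 As atoms per formula unit x 74.9216 g/mol,
#' reported in mg. With the default recipe (10 uL of 0.2 M As2O3) this is
#' 0.2997 mg, i.e. ~0.3 mg per sample analysis — 25-fold less than the
#' 7.5 mg consumed by the conventional UV-vis implementation of the assay.
#'
#' @param recipe A [reagent_recipe()].
#' @return Arsenic mass in mg.
#' @export
arsenic_mass_per_circle <- function(recipe = reagent_recipe()) {
  stopifnot(inherits(recipe, "reagent_recipe"))
  (recipe$arsenite_volume_ul * 1e-6) * recipe$arsenite_molarity * 2 *
    AS_ATOMIC_MASS * 1000
}

#' Arsenic mass on a whole card
#'
#' @inheritParams arsenic_mass_per_circle
#' @return `n_circles` times the per-circle mass, mg.
#' @export
arsenic_mass_per_card <- function(recipe = reagent_recipe()) {
  recipe$n_circles * arsenic_mass_per_circle(recipe)
}

#' Arsenic reduction factor versus a reference method
#'
#' Ratio of the arsenic mass a reference method consumes per sample to the
#' card's per-sample mass (7.5 mg for the UV-vis method vs 0.3 mg on card
#' gives the 25-fold reduction).
#'
#' @param reference_mass_mg Reference method's arsenic mass per sample, mg.
#' @param card_mass_per_sample_mg Card's arsenic mass per sample, mg.
#' @return Unitless ratio.
#' @export
reduction_factor <- function(reference_mass_mg,
                             card_mass_per_sample_mg = 0.3) {
  if (reference_mass_mg <= 0 || card_mass_per_sample_mg <= 0) {
    stop("masses must be positive", call. = FALSE)
  }
  reference_mass_mg / card_mass_per_sample_mg
}

#' Theoretical TCLP leachate concentration
#'
#' The EPA toxicity characteristic leaching procedure agitates solid waste
#' in extraction fluid at a 20:1 fluid-to-solid mass ratio (fluid density
#' taken as 1 g/mL), so a card of mass `card_mass_g` yields
#' `20 * card_mass_g / 1000` litres of leachate and
#' `ppm = as_mass_mg / volume_L`.
#'
#' @param as_mass_mg Leachable arsenic mass, mg.
#' @param card_mass_g Mass of the solid (card), g.
#' @param ratio Fluid-to-solid mass ratio (EPA standard: 20).
#' @return Concentration in ppm (mg/L).
#' @export
tclp_leachate_ppm <- function(as_mass_mg, card_mass_g, ratio = 20) {
  if (card_mass_g <= 0 || ratio <= 0) {
    stop("card mass and ratio must be positive", call. = FALSE)
  }
  if (as_mass_mg < 0) stop("arsenic mass must be non-negative", call. = FALSE)
  as_mass_mg / (ratio * card_mass_g / 1000)
}

#' Substitute the method LOD for undetectable measurements
#'
#' Conservative censoring rule for leachate results: a measurement reported
#' as undetectable is replaced by the method limit of detection, so summary
#' remediation estimates are lower bounds on performance. A detected value
#' below the LOD is kept but triggers a warning (inconsistent instrument
#' report).
#'
#' @param values Numeric vector of measured concentrations, ppm;
#'   undetectable entries may be `NA`.
#' @param detected Logical vector; `FALSE` marks undetectable entries.
#'   Defaults to `!is.na(values)`.
#' @param lod Method limit of detection, ppm (> 0).
#' @return Numeric vector with undetectable entries replaced by `lod`.
#' @examples
#' censor_below_lod(c(NA, NA, 0.5), lod = 0.028)
#' @export
censor_below_lod <- function(values, detected = !is.na(values), lod = 0.028) {
  if (lod <= 0) stop("LOD must be positive", call. = FALSE)
  if (length(detected) != length(values)) {
    stop("`detected` must match `values` in length", call. = FALSE)
  }
  if (any(detected & !is.na(values) & values < lod)) {
    warning("detected value below the method LOD: inconsistent instrument report")
  }
  out <- values
  out[!detected] <- lod
  out
}

#' Method limit of detection after dilution
#'
#' The effective (method) LOD when samples are diluted before measurement:
#' instrument LOD times the dilution factor (0.0028 ppm instrument LOD and a
#' ten-fold leachate dilution give the 0.028 ppm method LOD).
#'
#' @param instrument_lod_ppm Instrument-level LOD, ppm.
#' @param dilution_factor Fold dilution applied to the sample.
#' @return Method LOD in ppm.
#' @export
method_lod <- function(instrument_lod_ppm = 0.0028, dilution_factor = 10) {
  if (instrument_lod_ppm <= 0 || dilution_factor <= 0) {
    stop("LOD and dilution factor must be positive", call. = FALSE)
  }
  instrument_lod_ppm * dilution_factor
}

#' Percent of leachable arsenic removed
#'
#' @param baseline_ppm Pre-remediation leachate concentration, ppm (> 0).
#' @param residual_ppm Post-remediation concentration, ppm (in
#'   \[0, baseline\]).
#' @return Percentage `100 * (1 - residual / baseline)`.
#' @examples
#' percent_remediation(28.8, 0.7)  # 97.57
#' @export
percent_remediation <- function(baseline_ppm, residual_ppm) {
  if (baseline_ppm <= 0) stop("baseline must be positive", call. = FALSE)
  if (any(residual_ppm < 0)) stop("residual must be non-negative", call. = FALSE)
  if (any(residual_ppm > baseline_ppm)) {
    stop("residual exceeds baseline: not a remediation", call. = FALSE)
  }
  100 * (1 - residual_ppm / baseline_ppm)
}

#' Percent recovery of a theoretical level
#'
#' Measured concentration as a percentage of the theoretical value (e.g.
#' 28.78 ppm measured against the 28.82 ppm theoretical leachate level is a
#' 99.9% recovery).
#'
#' @param measured_ppm,theoretical_ppm Concentrations, ppm.
#' @return Percentage `100 * measured / theoretical`.
#' @export
percent_recovery <- function(measured_ppm, theoretical_ppm) {
  if (theoretical_ppm <= 0) stop("theoretical level must be positive",
                                 call. = FALSE)
  if (measured_ppm < 0) stop("measured level must be non-negative",
                             call. = FALSE)
  100 * measured_ppm / theoretical_ppm
}

#' EPA hazard classification of a leachate
#'
#' Solid waste is non-hazardous when its TCLP leachate arsenic is strictly
#' below the regulatory limit of 5 ppm.
#'
#' @param residual_ppm Leachate arsenic concentration(s), ppm (>= 0).
#' @param limit_ppm Regulatory limit, ppm.
#' @return Factor with levels `nonhazardous`, `hazardous`.
#' @examples
#' classify_hazard(c(0.7, 28.78))
#' @export
classify_hazard <- function(residual_ppm, limit_ppm = 5) {
  if (any(residual_ppm < 0)) stop("residual must be non-negative", call. = FALSE)
  factor(ifelse(residual_ppm < limit_ppm, "nonhazardous", "hazardous"),
         levels = c("nonhazardous", "hazardous"))
}

#' Arsenic mass budget for one card
#'
#' Per-circle and per-card arsenic mass, the TCLP leachate volume, and the
#' theoretical leachate concentration. The default card mass of 4.68 g is a
#' parameter: it is the solid mass consistent with the theoretical
#' 28.82 ppm starting leachate level under the standard 20:1 TCLP ratio.
#'
#' @param recipe A [reagent_recipe()].
#' @param card_mass_g Mass of the assay module, g.
#' @param ratio TCLP fluid-to-solid mass ratio.
#' @return A list of class `arsenic_budget`.
#' @export
arsenic_budget <- function(recipe = reagent_recipe(), card_mass_g = 4.68,
                           ratio = 20) {
  per_circle <- arsenic_mass_per_circle(recipe)
  per_card <- arsenic_mass_per_card(recipe)
  vol <- ratio * card_mass_g / 1000
  structure(
    list(as_mass_per_circle_mg = per_circle,
         as_mass_per_card_mg = per_card,
         card_mass_g = card_mass_g,
         liquid_to_solid_ratio = ratio,
         leachate_volume_l = vol,
         theoretical_leachate_ppm = tclp_leachate_ppm(per_card, card_mass_g,
                                                      ratio)),
    class = "arsenic_budget")
}

#' @export
print.arsenic_budget <- function(x, ...) {
  cat(sprintf("<arsenic_budget> %.4f mg As/circle, %.3f mg As/card\n",
              x$as_mass_per_circle_mg, x$as_mass_per_card_mg))
  cat(sprintf("  TCLP: %.3f L leachate (%g:1 on %.2f g) -> %.2f ppm theoretical\n",
              x$leachate_volume_l, x$liquid_to_solid_ratio, x$card_mass_g,
              x$theoretical_leachate_ppm))
  invisible(x)
}

#' Remediation outcome for a batch of cards
#'
#' Applies LOD censoring to a batch of post-remediation leachate
#' measurements, summarises the residual (mean of censored values), computes
#' the percent of arsenic removed relative to the baseline, and classifies
#' each card and the batch against the EPA limit.
#'
#' @param residual_ppm Measured post-remediation concentrations, ppm
#'   (`NA` = undetectable).
#' @param detected Logical; `FALSE` marks undetectable entries.
#' @param baseline_ppm Pre-remediation leachate level, ppm.
#' @param lod Method LOD substituted for undetectable entries, ppm.
#' @param limit_ppm EPA hazard limit, ppm.
#' @return A list of class `remediation_outcome`: `censored_ppm`,
#'   `mean_residual_ppm`, `percent_removed`, `per_card_hazard`, `hazard`,
#'   `n_undetectable`.
#' @export
remediation_outcome <- function(residual_ppm, detected = !is.na(residual_ppm),
                                baseline_ppm = 28.82, lod = method_lod(),
                                limit_ppm = 5) {
  cens <- censor_below_lod(residual_ppm, detected, lod)
  mean_res <- mean(cens)
  structure(
    list(baseline_ppm = baseline_ppm, method_lod_ppm = lod,
         censored_ppm = cens, mean_residual_ppm = mean_res,
         percent_removed = percent_remediation(baseline_ppm, mean_res),
         per_card_hazard = classify_hazard(cens, limit_ppm),
         hazard = classify_hazard(mean_res, limit_ppm),
         n_undetectable = sum(!detected)),
    class = "remediation_outcome")
}

#' @export
print.remediation_outcome <- function(x, ...) {
  cat(sprintf("<remediation_outcome> %d cards (%d below LOD %.3f ppm)\n",
              length(x$censored_ppm), x$n_undetectable, x$method_lod_ppm))
  cat(sprintf("  mean residual %.3f ppm of %.2f ppm baseline: %.1f%% removed, %s\n",
              x$mean_residual_ppm, x$baseline_ppm, x$percent_removed,
              as.character(x$hazard)))
  invisible(x)
}
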