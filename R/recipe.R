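#' Reagent recipe for one test card
#'
#' Fixed per-circle reagent volumes and the remediation-module constants.
#' Defaults follow the card protocol: 50 uL of sample or standard, 2 uL of
#' 0.12 M ferroin, 4 uL of 0.4 M ceric ammonium nitrate in 0.5 M sulfuric
#' acid, and 10 uL of 0.2 M arsenic trioxide in 0.15 M NaOH, for each of the
#' nine circles; the remediation module is pre-loaded with 60 mg oxone and
#' receives 0.9 g goethite (0.6 g is the minimum that brings leachate below
#' the hazard limit).
#'
#' @param sample_volume_ul Sample/standard volume per circle, uL.
#' @param ferroin_volume_ul,ferroin_molarity Indicator volume (uL) and
#'   concentration (M).
#' @param ceric_volume_ul,ceric_molarity Oxidant volume (uL) and
#'   concentration (M).
#' @param arsenite_volume_ul,arsenite_molarity As2O3 volume (uL) and
#'   concentration (M).
#' @param n_circles Reaction circles per card.
#' @param goethite_loaded_g,goethite_minimum_g Goethite mass added to the
#'   remediation module and the minimum effective mass, g.
#' @param oxone_mass_mg Oxidant pre-loaded in the remediation module, mg.
#' @return An object of class `reagent_recipe`.
#' @export
reagent_recipe <- function(sample_volume_ul = 50.0,
                           ferroin_volume_ul = 2.0, ferroin_molarity = 0.12,
                           ceric_volume_ul = 4.0, ceric_molarity = 0.4,
                           arsenite_volume_ul = 10.0, arsenite_molarity = 0.2,
                           n_circles = 9L,
                           goethite_loaded_g = 0.9, goethite_minimum_g = 0.6,
                           oxone_mass_mg = 60) {
  r <- structure(
    list(sample_volume_ul = sample_volume_ul,
         ferroin_volume_ul = ferroin_volume_ul,
         ferroin_molarity = ferroin_molarity,
         ceric_volume_ul = ceric_volume_ul,
         ceric_molarity = ceric_molarity,
         arsenite_volume_ul = arsenite_volume_ul,
         arsenite_molarity = arsenite_molarity,
         n_circles = as.integer(n_circles),
         goethite_loaded_g = goethite_loaded_g,
         goethite_minimum_g = goethite_minimum_g,
         oxone_mass_mg = oxone_mass_mg),
    class = "reagent_recipe")
  num <- unlist(r[c("sample_volume_ul", "ferroin_volume_ul", "ferroin_molarity",
                    "ceric_volume_ul", "ceric_molarity", "arsenite_molarity",
                    "n_circles", "goethite_loaded_g", "goethite_minimum_g",
                    "oxone_mass_mg")])
  if (any(num <= 0)) stop("recipe volumes, molarities and masses must be positive",
                          call. = FALSE)
  if (arsenite_volume_ul < 0) stop("arsenite volume must be non-negative",
                                   call. = FALSE)
  if (goethite_loaded_g < goethite_minimum_g) {
    stop("loaded goethite must be at least the effective minimum", call. = FALSE)
  }
  r
}

#' Artificial urine matrix specification
#'
#' Iodide concentration plus the fixed matrix constituents of the simulated
#' urine diluent used for validation standards: 15,000 ppm urea, 3800 ppm
#' chloride, 1800 ppm sodium, 1200 ppm potassium.
#'
#' @param iodide_conc Iodide concentration, ug I/L (>= 0).
#' @param urea_ppm,chloride_ppm,sodium_ppm,potassium_ppm Matrix constituents.
#' @return An object of class `solution_spec`.
#' @export
solution_spec <- function(iodide_conc, urea_ppm = 15000, chloride_ppm = 3800,
                          sodium_ppm = 1800, potassium_ppm = 1200) {
  if (!is.numeric(iodide_conc) || iodide_conc < 0) {
    stop("iodide concentration must be non-negative", call. = FALSE)
  }
  structure(list(iodide_conc = iodide_conc, urea_ppm = urea_ppm,
                 chloride_ppm = chloride_ppm, sodium_ppm = sodium_ppm,
                 potassium_ppm = potassium_ppm),
            class = "solution_spec")
}
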