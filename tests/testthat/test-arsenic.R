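test_that("the recipe delivers ~0.3 mg arsenic per circle and 9x per card", {
  m <- arsenic_mass_per_circle()
  expect_equal(m, 10e-6 * 0.2 * 2 * 74.9216 * 1000, tolerance = 1e-12)
  expect_equal(round(m, 1), 0.3)
  expect_equal(arsenic_mass_per_card(), 9 * m, tolerance = 1e-12)
  expect_equal(round(arsenic_mass_per_card(), 3), 2.697)
  # zero arsenite volume is allowed and gives zero mass
  r0 <- reagent_recipe(arsenite_volume_ul = 0)
  expect_equal(arsenic_mass_per_circle(r0), 0)
})

test_that("the card needs 25-fold less arsenic than the reference method", {
  expect_equal(reduction_factor(7.5, 0.3), 25)
  expect_equal(reduction_factor(1, 1), 1)
  expect_equal(reduction_factor(7.5, arsenic_mass_per_circle()), 25.03,
               tolerance = 1e-3)
  expect_error(reduction_factor(-1, 0.3), "positive")
  expect_error(reduction_factor(7.5, 0), "positive")
})

test_that("TCLP leachate concentration follows the 20:1 mass-ratio arithmetic", {
  ppm <- tclp_leachate_ppm(arsenic_mass_per_card(), card_mass_g = 4.68)
  expect_equal(round(ppm, 2), 28.82)
  expect_equal(round(ppm, 1), 28.8)
  # linear in As mass, inverse in card mass
  expect_equal(tclp_leachate_ppm(2, 4.68), 2 * tclp_leachate_ppm(1, 4.68))
  expect_equal(tclp_leachate_ppm(1, 9.36), tclp_leachate_ppm(1, 4.68) / 2)
  expect_equal(tclp_leachate_ppm(0, 4.68), 0)
  expect_error(tclp_leachate_ppm(1, 0), "positive")
  # round trip: ppm times leachate volume recovers the mass
  b <- arsenic_budget()
  expect_equal(b$theoretical_leachate_ppm * b$leachate_volume_l,
               b$as_mass_per_card_mg, tolerance = 1e-12)
})

test_that("LOD substitution censors undetectable values conservatively", {
  expect_equal(censor_below_lod(NA_real_, lod = 0.028), 0.028)
  expect_equal(censor_below_lod(0.5), 0.5)
  cens <- censor_below_lod(c(NA, NA, 0.5), lod = 0.028)
  expect_equal(mean(cens), (0.028 + 0.028 + 0.5) / 3)
  expect_equal(round(mean(cens), 4), 0.1853)
  expect_warning(censor_below_lod(0.01, detected = TRUE, lod = 0.028),
                 "below the method LOD")
  expect_equal(method_lod(0.0028, 10), 0.028)
  # with all values undetectable the remediation estimate decreases in the LOD
  lods <- c(0.01, 0.028, 0.1, 1)
  rem <- vapply(lods, function(l) {
    percent_remediation(28.82, mean(censor_below_lod(rep(NA_real_, 5), lod = l)))
  }, numeric(1))
  expect_true(all(diff(rem) < 0))
})

test_that("percent remediation and recovery reproduce the headline figures", {
  expect_equal(round(percent_remediation(28.8, 0.7), 1), 97.6)
  expect_equal(round(percent_remediation(28.8, 0.7), 2), 97.57)
  expect_equal(percent_remediation(10, 10), 0)
  expect_equal(percent_remediation(10, 0), 100)
  expect_error(percent_remediation(10, 11), "exceeds")
  expect_equal(round(percent_recovery(28.78, 28.82), 1), 99.9)
})

test_that("hazard classification uses the strict 5 ppm limit", {
  expect_equal(as.character(classify_hazard(28.78)), "hazardous")
  expect_equal(as.character(classify_hazard(0.7)), "nonhazardous")
  expect_equal(as.character(classify_hazard(5)), "hazardous")
  expect_equal(as.character(classify_hazard(4.999)), "nonhazardous")
})

test_that("remediation outcome summarises a batch like the 20-card experiment", {
  # 16 undetectable + 4 detected around 0.7 ppm
  resid <- c(rep(NA_real_, 16), 0.2, 0.5, 0.9, 1.2)
  out <- remediation_outcome(resid, baseline_ppm = 28.82)
  expect_equal(out$n_undetectable, 16)
  expect_equal(out$mean_residual_ppm,
               (16 * 0.028 + 0.2 + 0.5 + 0.9 + 1.2) / 20)
  expect_true(all(out$per_card_hazard == "nonhazardous"))
  expect_equal(as.character(out$hazard), "nonhazardous")
  expect_gt(out$percent_removed, 97)
  # an undetectable-only batch removes > 99.9%
  all_nd <- remediation_outcome(rep(NA_real_, 16), baseline_ppm = 28.82)
  expect_gt(all_nd$percent_removed, 99.9)
})
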