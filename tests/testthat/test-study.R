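test_that("study manifests have one card per solution per analyst", {
  lay <- test_layout()
  st <- generate_validation_study(n_solutions = 4, n_analysts = 2,
                                  layout = lay, seed = 5)
  expect_equal(nrow(st$manifest), 8)
  expect_equal(length(st$images), 8)
  counts <- table(st$manifest$solution_id, st$manifest$analyst_id)
  expect_true(all(counts == 1))
  expect_true(all(is.finite(st$manifest$true_conc)))

  st1 <- generate_validation_study(n_solutions = 1, n_analysts = 1,
                                   layout = lay, seed = 5)
  expect_equal(nrow(st1$manifest), 1)

  expect_error(generate_validation_study(n_solutions = 0, layout = lay),
               "positive")
  expect_error(generate_validation_study(conc_range = c(300, 100), layout = lay),
               "increasing")
})

test_that("identical seeds give identical studies, different seeds differ", {
  lay <- test_layout()
  a <- generate_validation_study(n_solutions = 2, n_analysts = 1,
                                 layout = lay, seed = 77)
  b <- generate_validation_study(n_solutions = 2, n_analysts = 1,
                                 layout = lay, seed = 77)
  expect_identical(a$manifest, b$manifest)
  expect_identical(lapply(a$images, unclass), lapply(b$images, unclass))
  c <- generate_validation_study(n_solutions = 2, n_analysts = 1,
                                 layout = lay, seed = 78)
  expect_false(identical(a$manifest$true_conc, c$manifest$true_conc))
})

test_that("written studies round-trip through the manifest CSV", {
  lay <- test_layout()
  dir <- withr::local_tempdir()
  st <- generate_validation_study(n_solutions = 2, n_analysts = 1,
                                  layout = lay, seed = 3, dir = dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(man$image_path)))
  res <- analyze_study(list(images = NULL, manifest = man), lay)
  expect_equal(nrow(res), 2)
  expect_true(all(is.finite(res$estimate)))
})

test_that("in the linear regime estimates are unbiased over replicates", {
  # score-space propagation at a mid-range concentration, n = 200 studies
  m <- linear_model(score_noise_sd = 6)
  pred <- predict_study_error(m, concs = rep(150, 4), n_rep = 200, seed = 31)
  # mean error is within 3 Monte-Carlo standard errors of zero
  se <- sd(pred$bias_reps) / sqrt(pred$n_rep)
  expect_lt(abs(pred$bias_mean), 3 * se)
})

test_that("the analyzed pipeline is self-consistent with its own confusion matrix", {
  lay <- test_layout()
  st <- generate_validation_study(n_solutions = 6, n_analysts = 1,
                                  layout = lay, seed = 12)
  res <- analyze_study(st, lay)
  rep <- validate_study(res)
  cm <- rep$computer$confusion
  expect_equal(sum(cm), nrow(res))
  expect_equal(rep$computer$percent_correct, 100 * sum(diag(unclass(cm))) / sum(cm))
  expect_lt(abs(unname(rep$computer$kappa["linear"]) -
                kappa_double_sum(unclass(cm), "linear")), 1e-12)
})
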