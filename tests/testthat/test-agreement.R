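test_that("the blind-study confusion matrices give the published agreement", {
  # visual analysis: 56/60 correct, linear-weighted kappa 0.926
  expect_equal(percent_correct(visual_matrix), 100 * 56 / 60)
  expect_equal(round(percent_correct(visual_matrix)), 93)
  expect_equal(cohens_kappa(visual_matrix, "linear")$kappa, 25 / 27,
               tolerance = 1e-12)  # 0.9259...
  expect_equal(round(cohens_kappa(visual_matrix, "linear")$kappa, 3), 0.926)
  expect_equal(cohens_kappa(visual_matrix, "none")$kappa, 0.9,
               tolerance = 1e-12)

  # computer analysis: 53/60 correct, unweighted kappa 0.825
  expect_equal(percent_correct(computer_matrix), 100 * 53 / 60)
  expect_equal(round(percent_correct(computer_matrix)), 88)
  expect_equal(cohens_kappa(computer_matrix, "none")$kappa, 0.825,
               tolerance = 1e-12)
})

test_that("confusion_matrix tallies records independent of order", {
  true <- rep(iodine_categories, times = c(3, 2, 1))
  pred <- c("deficient", "deficient", "adequate", "adequate", "excessive",
            "excessive")
  cm <- confusion_matrix(true, pred)
  expect_equal(sum(cm), 6)
  expect_equal(unname(unclass(cm)["deficient", "deficient"]), 2L)
  perm <- sample(6)
  expect_equal(unclass(confusion_matrix(true[perm], pred[perm])), unclass(cm))
  expect_error(confusion_matrix(character(0), character(0)), "no records")
  # single record lands in its own cell
  one <- confusion_matrix("adequate", "adequate")
  expect_equal(sum(one), 1)
  expect_equal(unname(unclass(one)["adequate", "adequate"]), 1L)
})

test_that("kappa properties: perfect agreement, scale invariance, permutation", {
  for (w in c("none", "linear", "quadratic")) {
    diagm <- as_confusion_matrix(diag(c(5, 9, 2)))
    expect_equal(cohens_kappa(diagm, w)$kappa, 1)
    # multiplying all counts by a positive integer leaves kappa unchanged
    expect_equal(cohens_kappa(as_confusion_matrix(unclass(visual_matrix) * 7), w)$kappa,
                 cohens_kappa(visual_matrix, w)$kappa, tolerance = 1e-12)
  }
  # percent correct is invariant to relabelling categories consistently
  p <- c(3, 1, 2)
  permuted <- unclass(computer_matrix)[p, p]
  expect_equal(percent_correct(permuted), percent_correct(computer_matrix))
})

test_that("weighted kappa agrees with a direct double-sum oracle", {
  set.seed(42)
  for (i in 1:200) {
    cm <- matrix(rpois(9, 5), 3, 3)
    if (sum(cm) == 0 || sum(diag(cm)) == sum(cm)) next
    for (w in c("none", "linear", "quadratic")) {
      got <- tryCatch(cohens_kappa(as_confusion_matrix(cm), w)$kappa,
                      error = function(e) NA_real_)
      if (is.na(got)) next
      expect_equal(got, kappa_double_sum(cm, w), tolerance = 1e-12)
    }
  }
  # the general weighted formula with identity weights reduces to classic kappa
  cm <- unclass(visual_matrix)
  po <- sum(diag(cm)) / sum(cm)
  pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
  expect_equal(cohens_kappa(visual_matrix, "none")$kappa, (po - pe) / (1 - pe),
               tolerance = 1e-12)
})

test_that("degenerate marginals make kappa undefined", {
  cm <- matrix(0L, 3, 3)
  cm[1, 1] <- 10L
  expect_error(cohens_kappa(as_confusion_matrix(cm), "linear"), "undefined")
})
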