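mk_records <- function(true, est, analyst = 1, solution = seq_along(true)) {
  data.frame(true_conc = true, estimate = est,
             analyst_id = rep(analyst, length.out = length(true)),
             solution_id = solution,
             below_range_negative = est < 0,
             above_range_extrapolated = est > 300)
}

test_that("accuracy metrics compute MAE and signed bias", {
  r <- mk_records(c(100, 200, 150), c(120, 190, 170))
  a <- accuracy_metrics(r)
  expect_equal(a$mae, mean(c(20, 10, 20)))  # 50/3
  expect_equal(a$bias, 10)
  expect_equal(a$n_in_range, 3)

  exact <- mk_records(c(50, 150, 250), c(50, 150, 250))
  a2 <- accuracy_metrics(exact)
  expect_equal(a2$mae, 0)
  expect_equal(a2$bias, 0)
})

test_that("range exclusions mirror the 35-of-60 bookkeeping", {
  # 60 reads: 17 extrapolated above 300, 8 negative, 35 usable
  set.seed(9)
  est <- c(runif(35, 10, 290), runif(17, 301, 500), runif(8, -40, -1))
  r <- mk_records(rep(150, 60), est)
  a <- accuracy_metrics(r)
  expect_equal(a$n_total, 60)
  expect_equal(a$excluded_above_range, 17)
  expect_equal(a$excluded_negative, 8)
  expect_equal(a$n_in_range, 35)
  expect_equal(a$n_in_range + a$excluded_above_range + a$excluded_negative,
               a$n_total)
})

test_that("per-analyst bias and inter-operator precision pair by solution", {
  r <- rbind(
    mk_records(c(100, 200), c(110, 220), analyst = 1, solution = 1:2),
    mk_records(c(100, 200), c(90, 210), analyst = 2, solution = 1:2))
  a <- accuracy_metrics(r)
  expect_equal(a$per_analyst$bias[a$per_analyst$analyst_id == "1"], 15)
  expect_equal(a$per_analyst$bias[a$per_analyst$analyst_id == "2"], 0)
  expect_equal(a$inter_operator_mean_abs_diff, mean(c(20, 10)))
  expect_equal(a$inter_operator_n_pairs, 2L)

  # an out-of-range member drops the pair
  r2 <- rbind(
    mk_records(c(100, 200), c(110, 350), analyst = 1, solution = 1:2),
    mk_records(c(100, 200), c(90, 210), analyst = 2, solution = 1:2))
  a2 <- accuracy_metrics(r2)
  expect_equal(a2$inter_operator_n_pairs, 1L)
  expect_equal(a2$inter_operator_mean_abs_diff, 20)

  # inter-device precision is the sd of replicate cards of one solution
  a3 <- accuracy_metrics(r, inter_device = c(148, 152, 150, 155, 145))
  expect_equal(a3$inter_device_sd, sd(c(148, 152, 150, 155, 145)))
})

test_that("accuracy metrics reject empty or fully excluded inputs", {
  expect_error(accuracy_metrics(data.frame()), "non-empty")
  all_out <- mk_records(c(100, 100), c(400, -5))
  expect_error(accuracy_metrics(all_out), "no in-range")
})

test_that("population status takes the median over all estimates", {
  p <- population_status(c(150, 175, 200))
  expect_equal(p$median_conc, 175)
  expect_equal(as.character(p$category), "adequate")
  expect_equal(population_status(50)$median_conc, 50)
  expect_equal(as.character(population_status(50)$category), "deficient")
  # even n: midpoint of central order statistics, closed-left threshold
  p2 <- population_status(c(90, 110))
  expect_equal(p2$median_conc, 100)
  expect_equal(as.character(p2$category), "adequate")
  # flagged excessive estimates are NOT dropped from a survey median
  p3 <- population_status(c(80, 90, 350, 400))
  expect_equal(p3$median_conc, 220)
  expect_error(population_status(numeric(0)))
})
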