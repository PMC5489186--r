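# Independent oracles used to cross-check the package implementations.

# weighted Cohen's kappa by explicit double summation over cells
kappa_double_sum <- function(cm, weighting) {
  k <- nrow(cm)
  n <- sum(cm)
  w <- function(i, j) {
    d <- abs(i - j) / (k - 1)
    switch(weighting,
           none = as.numeric(i == j),
           linear = 1 - d,
           quadratic = 1 - d^2)
  }
  r <- rowSums(cm) / n
  cc <- colSums(cm) / n
  po <- 0
  pe <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      po <- po + w(i, j) * cm[i, j] / n
      pe <- pe + w(i, j) * r[i] * cc[j]
    }
  }
  unname((po - pe) / (1 - pe))
}

# closed-form simple linear regression (textbook least squares)
ols_closed_form <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - (intercept + slope * x)
  df <- length(x) - 2
  s2 <- sum(res^2) / df
  se_int <- sqrt(s2 * (1 / length(x) + mean(x)^2 / sxx))
  list(slope = slope, intercept = intercept, intercept_se = se_int)
}

# Table 1 of the blind validation study: rows = true category,
# columns = predicted (deficient, adequate, excessive)
visual_matrix <- as_confusion_matrix(rbind(c(20, 0, 0),
                                           c(1, 17, 2),
                                           c(0, 1, 19)))
computer_matrix <- as_confusion_matrix(rbind(c(16, 4, 0),
                                             c(0, 20, 0),
                                             c(0, 3, 17)))

# small, fast layout for image tests
test_layout <- function(dpi = 100) default_card_layout(dpi = dpi)

# colour model whose red-minus-blue score is exactly linear in concentration
# with integral channel steps, so rendered 8-bit colours are exact at
# concentrations that are multiples of 2.5 ug I/L
linear_model <- function(score_noise_sd = 0) {
  color_response_model(anchor_blank = c(60, 70, 190),
                       anchor_excessive = c(180, 70, 70),
                       response = "linear",
                       score_noise_sd = score_noise_sd)
}

noiseless_imaging <- function(...) {
  imaging_model(pixel_noise_sd = 0, illumination_gradient = 0, ...)
}
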