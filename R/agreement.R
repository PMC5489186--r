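#' Three-way confusion matrix of WHO iodine categories
#'
#' Tallies (true, predicted) category pairs into a 3 x 3 matrix with rows =
#' true category and columns = predicted, both ordered deficient, adequate,
#' excessive.
#'
#' @param true,predicted Vectors of categories (factor or character using
#'   the `iodine_categories` labels), or `true` may be a two-column data
#'   frame of (true, predicted) pairs.
#' @return Integer matrix of class `confusion_matrix3`.
#' @examples
#' confusion_matrix(c("deficient", "adequate"), c("deficient", "excessive"))
#' @export
confusion_matrix <- function(true, predicted = NULL) {
  if (is.null(predicted)) {
    stopifnot(is.data.frame(true), ncol(true) >= 2)
    predicted <- true[[2]]
    true <- true[[1]]
  }
  if (length(true) == 0L) stop("no records to tally", call. = FALSE)
  if (length(true) != length(predicted)) {
    stop("true and predicted must have the same length", call. = FALSE)
  }
  tt <- as_iodine_category(true)
  pp <- as_iodine_category(predicted)
  cm <- table(true = tt, predicted = pp)
  out <- matrix(as.integer(cm), 3, 3,
                dimnames = list(true = iodine_categories,
                                predicted = iodine_categories))
  class(out) <- c("confusion_matrix3", class(out))
  out
}

#' Build a confusion matrix directly from counts
#'
#' @param counts 3 x 3 matrix of non-negative integers (rows = true).
#' @return A `confusion_matrix3`.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be a 3 x 3 matrix of non-negative integers",
         call. = FALSE)
  }
  if (sum(counts) == 0) stop("confusion matrix must have a positive total",
                             call. = FALSE)
  out <- matrix(as.integer(counts), 3, 3,
                dimnames = list(true = iodine_categories,
                                predicted = iodine_categories))
  class(out) <- c("confusion_matrix3", class(out))
  out
}

#' Percent of correctly categorized reads
#'
#' @param cm A `confusion_matrix3` (or any 3 x 3 count matrix).
#' @return Percentage in \[0, 100\]: `100 * trace / total`.
#' @export
percent_correct <- function(cm) {
  cm <- unclass(as.matrix(cm))
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has zero total", call. = FALSE)
  100 * sum(diag(cm)) / total
}

#' Cohen's kappa for the three-way categorization
#'
#' Chance-corrected agreement `K = (Po - Pe) / (1 - Pe)`, where `Po` and
#' `Pe` are the weighted observed and expected (from the marginals)
#' agreement. Weights over the k = 3 ordered categories:
#' identity (`"none"`), `1 - |i - j| / (k - 1)` (`"linear"`), or
#' `1 - (|i - j| / (k - 1))^2` (`"quadratic"`). Linear and quadratic
#' weighting give partial credit to near-miss categories, which is the
#' natural choice for the ordered deficient/adequate/excessive scale;
#' because published kappa values for this kind of card data are ambiguous
#' about their weighting, all three are exposed and [validate_study()]
#' reports them side by side.
#'
#' @param cm A `confusion_matrix3` (or 3 x 3 count matrix, rows = true).
#' @param weighting `"none"`, `"linear"` or `"quadratic"`.
#' @return A list of class `agreement_result`: `kappa`, `weighting`,
#'   `percent_correct`, `po`, `pe`.
#' @examples
#' cm <- as_confusion_matrix(rbind(c(20, 0, 0), c(1, 17, 2), c(0, 1, 19)))
#' cohens_kappa(cm, "linear")$kappa  # 0.926
#' @export
cohens_kappa <- function(cm, weighting = c("linear", "none", "quadratic")) {
  weighting <- match.arg(weighting)
  cm <- unclass(as.matrix(cm))
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has zero total", call. = FALSE)
  P <- cm / total
  W <- kappa_weights(weighting, k = nrow(cm))
  po <- sum(W * P)
  pe <- sum(W * outer(rowSums(P), colSums(P)))
  if (isTRUE(all.equal(pe, 1))) {
    stop("kappa undefined: degenerate marginals give full chance agreement",
         call. = FALSE)
  }
  structure(list(kappa = (po - pe) / (1 - pe), weighting = weighting,
                 percent_correct = percent_correct(cm), po = po, pe = pe),
            class = "agreement_result")
}

kappa_weights <- function(weighting, k = 3) {
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  switch(weighting,
         none = (d == 0) * 1,
         linear = 1 - d,
         quadratic = 1 - d^2)
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> kappa %.4f (%s weights), %.1f%% correct\n",
              x$kappa, x$weighting, x$percent_correct))
  invisible(x)
}

#' @export
print.confusion_matrix3 <- function(x, ...) {
  print(matrix(as.integer(x), 3, 3,
               dimnames = list(true = iodine_categories,
                               predicted = iodine_categories)))
  invisible(x)
}
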