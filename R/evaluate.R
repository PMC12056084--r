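# Error metrics for validating hybrid index / heterozygosity estimates
# against known hybrid classes.

#' Accuracy of a set of estimates relative to a known expectation
#'
#' `1 - |mean(observed) - expected| / expected`. Deliberately unclamped:
#' gross errors yield negative accuracy. Undefined at `expected = 0`
#' (relative error has no scale there); use [mean_absolute_error()] for
#' parental classes.
#'
#' @param observed Numeric vector of per-individual estimates.
#' @param expected The class expectation, strictly positive.
#' @return A single accuracy value (1 = perfect).
#' @export
accuracy <- function(observed, expected) {
  if (length(observed) == 0) stop("no observations", call. = FALSE)
  if (length(expected) != 1 || !is.finite(expected) || expected <= 0) {
    stop("`expected` must be a single value > 0; accuracy is undefined ",
         "at 0 -- use mean_absolute_error() instead", call. = FALSE)
  }
  1 - abs(mean(observed) - expected) / expected
}

#' Precision of a set of estimates
#'
#' Mean absolute (Euclidean) distance of each observation from the mean
#' observation; smaller values indicate higher precision. For a matrix of
#' 2-D triangle-plot estimates (columns: hybrid index, heterozygosity)
#' the units are Euclidean distance on the plot; for a vector this is the
#' mean absolute deviation. Translation- and permutation-invariant.
#'
#' @param observed Numeric vector, or matrix/data frame with one row per
#'   individual.
#' @return A single nonnegative value.
#' @export
est_precision <- function(observed) {
  if (is.data.frame(observed)) observed <- as.matrix(observed)
  if (is.matrix(observed)) {
    if (nrow(observed) == 0) stop("no observations", call. = FALSE)
    centroid <- colMeans(observed)
    dev <- sweep(observed, 2, centroid)
    mean(sqrt(rowSums(dev^2)))
  } else {
    if (length(observed) == 0) stop("no observations", call. = FALSE)
    mean(abs(observed - mean(observed)))
  }
}

#' Mean absolute error against a known expected value
#'
#' Unlike [accuracy()], defined for `expected = 0`, so it covers parental
#' classes.
#'
#' @param observed Numeric vector of per-individual estimates.
#' @param expected The known expected value.
#' @return Mean of `|observed - expected|`.
#' @export
mean_absolute_error <- function(observed, expected) {
  if (length(observed) == 0) stop("no observations", call. = FALSE)
  mean(abs(observed - expected))
}

#' Fold a hybrid index onto distance from the nearest parental end
#'
#' Hybrid index lives on `[0, 1]` with a parental group at either end and
#' the ends arbitrary; estimates above 0.5 are subtracted from 1 so that
#' the folded value measures distance from the nearest parental extreme.
#' Symmetric: `fold(h) = fold(1 - h)`.
#'
#' @param h Hybrid index values in `[0, 1]` (vectorized).
#' @return Values in `[0, 0.5]`.
#' @export
fold_hybrid_index <- function(h) {
  if (any(h < 0 | h > 1, na.rm = TRUE)) {
    stop("hybrid index must lie in [0, 1]", call. = FALSE)
  }
  ifelse(h > 0.5, 1 - h, h)
}

#' Log-fold change between misassigned and reference estimates
#'
#' `log((est_mis + epsilon) / (est_ref + epsilon))`, natural log. With
#' hybrid-index inputs pre-folded via [fold_hybrid_index()], negative
#' values mean the estimate under parental misassignment shifted toward
#' the nearest parental extreme, positive values away from it.
#'
#' @param est_mis,est_ref Nonnegative estimates (vectorized).
#' @param epsilon Small positive stabilizer for zero estimates.
#' @return Signed log-fold changes.
#' @export
log_fold_change <- function(est_mis, est_ref, epsilon = 1e-6) {
  if (any(est_mis < 0, na.rm = TRUE) || any(est_ref < 0, na.rm = TRUE)) {
    stop("estimates must be nonnegative", call. = FALSE)
  }
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  log((est_mis + epsilon) / (est_ref + epsilon))
}

#' Per-class error metrics over a triangle table
#'
#' Joins a triangle table with known class assignments and the analytic
#' class expectations, and reports accuracy (hybrid classes only),
#' precision and MAE per class and axis, plus the 2-D Euclidean precision.
#'
#' @param table A triangle table from [build_triangle_table()].
#' @param classes Data frame with columns `id` and `class`; class labels
#'   must appear in [class_expectations()].
#' @param max_backcross Passed to [class_expectations()].
#' @return Data frame with one row per class.
#' @export
evaluate_classes <- function(table, classes, max_backcross = 4) {
  exp_tab <- class_expectations(max_backcross)
  unknown <- setdiff(unique(classes$class), exp_tab$class)
  if (length(unknown)) {
    stop("unknown class label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  merged <- merge(table, classes, by = "id")
  out <- lapply(split(merged, merged$class), function(d) {
    ex <- exp_tab[exp_tab$class == d$class[1], ]
    ok <- !is.na(d$hybrid_index) & !is.na(d$heterozygosity)
    d <- d[ok, ]
    acc <- function(obs, e) if (e > 0) accuracy(obs, e) else NA_real_
    data.frame(
      class = d$class[1], n = nrow(d),
      expected_hi = ex$hi, expected_het = ex$het,
      mean_hi = mean(d$hybrid_index), mean_het = mean(d$heterozygosity),
      accuracy_hi = acc(d$hybrid_index, ex$hi),
      accuracy_het = acc(d$heterozygosity, ex$het),
      precision_hi = est_precision(d$hybrid_index),
      precision_het = est_precision(d$heterozygosity),
      precision_2d = est_precision(d[, c("hybrid_index", "heterozygosity")]),
      mae_hi = mean_absolute_error(d$hybrid_index, ex$hi),
      mae_het = mean_absolute_error(d$heterozygosity, ex$het),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
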