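#' Coefficient of repeatability
#'
#' Root-mean-square form over test-retest differences:
#' `r = 1.96 * sqrt(sum(d^2) / n)`. Unlike the Bland-Altman limits of
#' agreement this form does not centre the differences, so a systematic
#' offset between acquisitions inflates it.
#'
#' @param d numeric vector of paired differences (first - second).
#' @param n number of subjects; defaults to `length(d)`.
#' @return non-negative scalar in the units of `d`.
#' @export
repeatability_coefficient <- function(d, n = length(d)) {
  if (length(d) == 0L) stop("validation error: no differences supplied")
  if (any(!is.finite(d))) stop("differences must be finite")
  1.96 * sqrt(sum(d^2) / n)
}

#' Bland-Altman repeatability analysis
#'
#' Differences `d = first - second`, their mean, limits of agreement
#' `mean(d) +/- 1.96 * SD(d)` (sample SD, n-1 denominator), the RMS-form
#' coefficient of repeatability, and the proportional-bias slope of `d`
#' against the pair means.
#'
#' @param first,second paired measurements (same length >= 2).
#' @return object of class `repeatability_result`: list with `d`, `n`,
#'   `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `r`,
#'   `proportional_bias_slope`.
#' @export
bland_altman <- function(first, second) {
  if (length(first) != length(second)) stop("paired vectors differ in length")
  if (length(first) < 2L) stop("validation error: need >= 2 pairs")
  d <- first - second
  m <- (first + second) / 2
  sd_d <- stats::sd(d)
  slope <- if (stats::var(m) > 0) unname(stats::coef(stats::lm(d ~ m))[2]) else 0
  structure(list(d = d, n = length(d), mean_diff = mean(d), sd_diff = sd_d,
                 loa_low = mean(d) - 1.96 * sd_d,
                 loa_high = mean(d) + 1.96 * sd_d,
                 r = repeatability_coefficient(d),
                 proportional_bias_slope = slope),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("repeatability: n=%d mean_diff=%.4g LoA=[%.4g, %.4g] r=%.4g\n",
              x$n, x$mean_diff, x$loa_low, x$loa_high, x$r))
  invisible(x)
}

#' @keywords internal
icc_band <- function(icc) {
  # quoted thresholds: <0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, >0.90 excellent
  if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc <= 0.9) "good"
  else "excellent"
}

#' @keywords internal
kappa_band <- function(k) {
  if (k < 0) "less than chance"
  else if (k <= 0.20) "slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost perfect"
}

#' Intraclass correlation, two-way random, absolute agreement, single rater
#'
#' ICC(2,1) from the mean-squares decomposition of a complete subjects x
#' raters table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' Absolute agreement penalises systematic rater offsets, matching
#' inter-reader agreement semantics. The interpretation band follows the
#' conventional thresholds (poor < 0.5, moderate, good, excellent > 0.90).
#'
#' @param ratings numeric matrix or data.frame, subjects in rows, raters in
#'   columns; complete (no NA).
#' @return object of class `agreement_result`: `icc`, `icc_band`, `form`,
#'   plus mean squares `ms`.
#' @export
icc_absolute_agreement <- function(ratings) {
  x <- as.matrix(ratings)
  if (any(!is.finite(x))) stop("validation error: incomplete ratings table")
  n <- nrow(x); k <- ncol(x)
  if (k < 2L) stop("validation error: need >= 2 raters")
  if (n < 3L) stop("validation error: need >= 3 subjects")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)
  SSE <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  icc <- if (denom == 0) 1 else (MSR - MSE) / denom
  structure(list(icc = icc, icc_band = icc_band(icc),
                 form = "ICC(2,1) two-way random, absolute agreement, single measurement",
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE)),
            class = "agreement_result")
}

#' Consistency-form ICC (two-way mixed, single rater)
#'
#' `(MSR - MSE) / (MSR + (k-1) MSE)`; ignores systematic rater offsets.
#' Provided for comparison with the absolute-agreement form.
#'
#' @inheritParams icc_absolute_agreement
#' @return scalar ICC(3,1).
#' @export
icc_consistency <- function(ratings) {
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  SSE <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR + (k - 1) * MSE == 0) 1 else (MSR - MSE) / (MSR + (k - 1) * MSE)
}

#' Quadratically weighted kappa for two raters
#'
#' Chance-corrected ordinal agreement with disagreement weights
#' `w_ij = (i - j)^2 / (k - 1)^2`:
#' `kappa = 1 - sum(w * o) / sum(w * e)`, where `o` are observed cell
#' proportions and `e` the chance-expected proportions from the marginal
#' products. Operates on the declared ordered category set, so categories a
#' rater never used still contribute structural zeros. The Landis-Koch
#' interpretation band is attached.
#'
#' @param rater1,rater2 vectors of ratings (coercible to the levels).
#' @param levels ordered category set; defaults to the sorted union of
#'   observed ratings.
#' @return object of class `agreement_result`: `kappa_w`, `kappa_band`,
#'   `table` (k x k contingency counts).
#' @export
weighted_kappa <- function(rater1, rater2, levels = NULL) {
  if (length(rater1) != length(rater2)) stop("rating vectors differ in length")
  if (is.null(levels)) levels <- sort(unique(c(rater1, rater2)))
  k <- length(levels)
  if (k < 2L) stop("validation error: need >= 2 ordered categories")
  f1 <- factor(rater1, levels = levels)
  f2 <- factor(rater2, levels = levels)
  if (any(is.na(f1)) || any(is.na(f2))) {
    stop("ratings outside the declared category set")
  }
  tab <- table(f1, f2)
  n <- sum(tab)
  o <- tab / n
  e <- outer(rowSums(o), colSums(o))
  w <- outer(seq_len(k), seq_len(k), function(i, j) (i - j)^2) / (k - 1)^2
  denom <- sum(w * e)
  kap <- if (denom == 0) 1 else 1 - sum(w * o) / denom
  structure(list(kappa_w = kap, kappa_band = kappa_band(kap), table = tab),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  if (!is.null(x$icc)) {
    cat(sprintf("ICC = %.4f (%s); %s\n", x$icc, x$icc_band, x$form))
  }
  if (!is.null(x$kappa_w)) {
    cat(sprintf("weighted kappa = %.4f (%s)\n", x$kappa_w, x$kappa_band))
  }
  invisible(x)
}
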