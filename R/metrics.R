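#' Mean squared error
#'
#' @param y_true,y_pred Equal-length numeric vectors (length >= 1).
#' @return Mean of squared residuals.
#' @export
mse <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  mean((y_true - y_pred)^2)
}

#' Sample distance correlation
#'
#' Computes the sample distance correlation (energy-statistics V-statistic
#' version): pairwise Euclidean distance matrices of `x` and `y` are double
#' centered, \eqn{\mathrm{dCov}^2} is the mean of their elementwise product,
#' and \eqn{\mathrm{dCor} = \mathrm{dCov} / \sqrt{\mathrm{dVar}_x\,
#' \mathrm{dVar}_y}}. Returns 0 by convention when either distance variance
#' is 0 (constant input). The biased V-statistic (not the bias-corrected
#' estimator) is used, the common default.
#'
#' dCor is symmetric in its arguments and invariant to shifts and positive
#' rescalings; it equals 1 under exact affine dependence.
#'
#' @param x,y Numeric vectors of equal length n >= 2.
#' @return A number in `[0, 1]`.
#' @export
dcor <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  if (length(y) != n) stop("length mismatch")
  A <- dcenter(abs(outer(x, x, "-")))
  B <- dcenter(abs(outer(y, y, "-")))
  dcov2 <- mean(A * B)
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  r2 <- dcov2 / sqrt(dvx * dvy)
  sqrt(max(r2, 0))
}

dcenter <- function(D) {
  rm_ <- rowMeans(D)
  D - outer(rm_, rep(1, ncol(D))) - outer(rep(1, nrow(D)), colMeans(D)) + mean(D)
}

#' Weight sparsity report
#'
#' Counts bit-exact zeros in a (concatenated) penalized-weight vector; no
#' epsilon thresholding is applied, since the proximal operators of the
#' thresholding penalties produce literal zeros. The headline "sparsity (%)"
#' used in reports is `zero_fraction * 100` (the percentage of weights set
#' to zero); the nonzero fraction \eqn{\|w\|_0 / d} is also exposed.
#'
#' @param weights Nonempty numeric vector.
#' @return Object of class `"sparsity_report"` with fields `d`, `n_nonzero`,
#'   `zero_fraction`, `nonzero_fraction`.
#' @export
sparsity <- function(weights) {
  if (length(weights) == 0L) stop("empty weight vector")
  d <- length(weights)
  nz <- sum(weights != 0)
  structure(list(d = d, n_nonzero = nz,
                 zero_fraction = (d - nz) / d,
                 nonzero_fraction = nz / d),
            class = "sparsity_report")
}

#' @export
print.sparsity_report <- function(x, ...) {
  cat(sprintf("sparsity: %.2f%% of %d weights are exactly zero (%d nonzero)\n",
              100 * x$zero_fraction, x$d, x$n_nonzero))
  invisible(x)
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided exact Wilcoxon signed-rank test for paired samples. Zero
#' differences are dropped (Wilcoxon's original treatment); the absolute
#' differences are ranked with mid-ranks for ties; `W` is the sum of ranks of
#' the positive differences. The p-value is exact: the null distribution of
#' `W` is obtained by enumerating all \eqn{2^n} sign assignments of the
#' observed ranks (via a generating-function convolution, so ties are
#' handled exactly), and the two-sided p is
#' \eqn{\min(1, 2\min(P(W \le w), P(W \ge w)))}.
#'
#' @param a,b Equal-length paired numeric vectors; after dropping zero
#'   differences, between 1 and 25 pairs must remain.
#' @return List with `statistic` (W), `p_value`, and `n_used`.
#' @examples
#' wilcoxon_signed_rank_exact(2:11, 1:10)$p_value  # 2 / 1024
#' @export
wilcoxon_signed_rank_exact <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("no nonzero pairs")
  if (n > 25L) stop("exact enumeration supports at most 25 nonzero pairs")
  r <- rank(abs(d))               # mid-ranks for ties
  W <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))  # doubled mid-ranks are integers
  # counts[s + 1] = number of sign assignments with doubled rank-sum s
  counts <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts)
    counts <- c(counts, numeric(ri)) + shifted
  }
  total <- 2^n
  w2 <- as.integer(round(2 * W))
  sums <- seq_along(counts) - 1L
  p_le <- sum(counts[sums <= w2]) / total
  p_ge <- sum(counts[sums >= w2]) / total
  list(statistic = W, p_value = min(1, 2 * min(p_le, p_ge)), n_used = n)
}

#' Format mean and sample standard deviation
#'
#' Renders a vector of repeated measurements as `"m (s)"` with the given
#' number of decimals, the layout used in the package's result tables.
#'
#' @param values Numeric vector of at least 2 values.
#' @param decimals Number of decimals (default 3).
#' @return A character scalar such as `"0.133 (0.002)"`.
#' @export
format_mean_std <- function(values, decimals = 3L) {
  if (length(values) < 2L) stop("need at least 2 values")
  sprintf(paste0("%.", decimals, "f (%.", decimals, "f)"),
          mean(values), stats::sd(values))
}
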