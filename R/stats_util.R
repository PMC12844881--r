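# Statistical primitives used by the feature analyses: Deming
# (errors-in-variables) regression, correlations with pairwise-complete
# missing handling, and simple linear regression.

#' Deming errors-in-variables regression
#'
#' Closed-form fit of `y = a + b x` allowing measurement error in both
#' variables, with error-variance ratio `lambda` (`lambda = 1` is orthogonal
#' regression).  With moment sums `s_xx`, `s_yy`, `s_xy`,
#' `b = (s_yy - lambda s_xx + sqrt((s_yy - lambda s_xx)^2 +
#' 4 lambda s_xy^2)) / (2 s_xy)` and `a = ybar - b xbar`.  Pairs with a
#' missing coordinate are dropped.
#'
#' @param x,y numeric vectors of equal length.
#' @param lambda ratio of the y- to x-error variances (default 1).
#' @return list of class `"deming_fit"`: `slope`, `intercept`, `lambda`,
#'   `n_pairs`, `degenerate` (TRUE when `s_xy = 0` and the fit is vertical
#'   or undefined).
#' @export
deming_fit <- function(x, y, lambda = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (lambda <= 0) stop("lambda must be positive")
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  if (sxx == 0 && syy == 0) stop("degenerate input: both variables constant")
  if (sxy == 0) {
    # no covariance: slope 0 if x carries the variance, vertical otherwise
    res <- list(slope = if (syy > lambda * sxx) NA_real_ else 0,
                intercept = if (syy > lambda * sxx) NA_real_ else mean(y),
                lambda = lambda, n_pairs = n, degenerate = TRUE)
    class(res) <- "deming_fit"
    return(res)
  }
  b <- (syy - lambda * sxx +
          sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) / (2 * sxy)
  res <- list(slope = b, intercept = mean(y) - b * mean(x),
              lambda = lambda, n_pairs = n, degenerate = FALSE)
  class(res) <- "deming_fit"
  res
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming regression (lambda = %g, n = %d)\n", x$lambda, x$n_pairs))
  if (x$degenerate) cat("  degenerate fit\n")
  cat(sprintf("  slope = %.4g, intercept = %.4g\n", x$slope, x$intercept))
  invisible(x)
}

#' Correlation with pairwise-complete handling
#'
#' Pearson or Spearman correlation on the pairwise-complete subset, with the
#' two-tailed p-value from the t approximation; the number of complete pairs
#' is reported so the caller can see how much was dropped (features such as
#' spike threshold are undefined for non-spiking cells by construction and
#' are never imputed).
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `n_pairs`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = method,
                                  exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = sum(ok),
       method = method)
}

#' Ordinary least-squares line
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @return list with `slope` and `intercept`.
#' @export
simple_linreg <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 complete pairs")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("x is constant")
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  list(slope = b, intercept = mean(y) - b * mean(x))
}
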