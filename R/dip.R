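#' Hartigan dip statistic of unimodality
#'
#' Computes the dip statistic of a numeric sample: the minimal sup-norm
#' distance between the empirical CDF and the closest unimodal CDF, i.e. a
#' nondecreasing distribution function that is convex up to its mode and
#' concave beyond it (the greatest-convex-minorant / least-concave-majorant
#' geometry).  The statistic is found by bisection on the band half-width
#' `d`: the sample admits a unimodal CDF within `d` exactly when a taut
#' string threaded through the `+/- d` gates around the ECDF has a slope
#' sequence that rises and then falls.
#'
#' The dip is invariant under strictly increasing affine transforms of the
#' data and, for samples without ties, lies in `[1/(2n), 1/4]`.  Tied values
#' are merged into single ECDF knots and a single atom (jump) of the fitted
#' CDF is allowed at a tied knot, so heavily discretised samples remain
#' well behaved.
#'
#' @param x numeric vector, at least 4 finite values.
#' @return the dip statistic (a single number).
#' @seealso [dip_test()] for a bootstrap p-value.
#' @export
dip_stat <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("`x` must be finite and non-missing")
  if (length(x) < 4L) stop("dip statistic needs at least 4 observations")
  .dip_stat_cpp(x)
}

#' Dip test of unimodality with a bootstrap p-value
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution.  The p-value is the fraction of `n_boot` uniform(0, 1)
#' samples of the same size whose dip statistic is at least as large as the
#' observed one; the uniform is the standard least-favourable reference
#' distribution for the dip.
#'
#' @param x numeric vector, at least 4 finite values.
#' @param n_boot number of null bootstrap draws (default 10000).
#' @param seed optional integer seed for the bootstrap draws.
#' @return a list with elements `dip`, `p_value`, `n`, and `n_boot`,
#'   of class `"dip_test"`.
#' @examples
#' set.seed(1)
#' bimodal <- c(rnorm(100, 0.35, 0.05), rnorm(100, 0.95, 0.15))
#' dip_test(bimodal, n_boot = 200, seed = 1)
#' @export
dip_test <- function(x, n_boot = 10000L, seed = NULL) {
  stat <- dip_stat(x)
  n <- length(x)
  if (n_boot < 1L) stop("`n_boot` must be positive")
  if (!is.null(seed)) set.seed(seed)
  null_dips <- .dip_null_cpp(as.integer(n), as.integer(n_boot))
  p <- mean(null_dips >= stat)
  structure(list(dip = stat, p_value = p, n = n, n_boot = n_boot),
            class = "dip_test")
}

#' @export
print.dip_test <- function(x, ...) {
  cat("Hartigan dip test of unimodality\n")
  cat(sprintf("  dip = %.5f, n = %d\n", x$dip, x$n))
  cat(sprintf("  bootstrap p-value = %.4g (%d uniform-null draws)\n",
              x$p_value, x$n_boot))
  invisible(x)
}
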