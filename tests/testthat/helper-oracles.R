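# Independent oracles used by the tests.  These deliberately re-derive each
# quantity by brute force or closed form, never through the package's own
# code path.

# Dip statistic by linear programming: minimal sup deviation over unimodal
# piecewise-linear CDFs anchored far outside the data, enumerating the
# position of the slope peak.  Mirrors the statistic's definition exactly;
# tractable for small n.
dip_lp_oracle <- function(x, A = 1e5) {
  x <- sort(x)
  n <- length(x)
  stopifnot(!anyDuplicated(x))
  xs <- (x - x[1]) / (x[n] - x[1])
  cum <- (1:n) / n
  pre <- (0:(n - 1)) / n
  xx <- c(-A, xs, 1 + A)
  nv <- n + 1                       # g_1..g_n then d
  slope_row <- function(j) {        # slope j between xx[j+1] and xx[j+2]
    r <- numeric(nv); c0 <- 0
    dx <- xx[j + 2] - xx[j + 1]
    if (j > 0) r[j] <- r[j] - 1
    if (j == n) c0 <- c0 + 1 else r[j + 1] <- r[j + 1] + 1
    list(r = r / dx, c0 = c0 / dx)
  }
  best <- Inf
  for (p in 0:n) {
    A1 <- NULL; b1 <- NULL
    add_le <- function(a, b) { A1 <<- rbind(A1, a); b1 <<- c(b1, b) }
    for (j in 0:(n - 1)) {
      sj <- slope_row(j); sj1 <- slope_row(j + 1)
      if (j < p) add_le(sj$r - sj1$r, sj1$c0 - sj$c0)   # slopes rise to p
      else       add_le(sj1$r - sj$r, sj$c0 - sj1$c0)   # then fall
    }
    for (i in 1:n) {
      a <- numeric(nv); a[i] <- 1; a[nv] <- -1
      add_le(a, pre[i])             # g_i - d <= (i-1)/n
      a <- numeric(nv); a[i] <- -1; a[nv] <- -1
      add_le(a, -cum[i])            # g_i + d >= i/n
      a <- numeric(nv); a[i] <- 1
      add_le(a, 1)
    }
    obj <- numeric(nv); obj[nv] <- 1
    neg <- b1 < 0
    fit <- try(boot::simplex(a = obj,
                             A1 = A1[!neg, , drop = FALSE], b1 = b1[!neg],
                             A2 = -A1[neg, , drop = FALSE], b2 = -b1[neg],
                             maxi = FALSE), silent = TRUE)
    if (!inherits(fit, "try-error") && fit$solved == 1)
      best <- min(best, fit$value)
  }
  best
}

# Optimal one-dimensional two-class partition by exhaustive search over all
# contiguous splits of the sorted values (the optimal 2-means partition in
# one dimension is always contiguous).
split2_brute <- function(durations) {
  o <- order(durations)
  xs <- durations[o]
  n <- length(xs)
  best <- Inf; best_k <- 1
  for (k in 1:(n - 1)) {
    a <- xs[1:k]; b <- xs[(k + 1):n]
    w <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (w < best) { best <- w; best_k <- k }
  }
  lab <- rep("wide", n)
  lab[o[1:best_k]] <- "narrow"     # sorted prefix holds the smaller values
  list(labels = lab, wcss = best)
}

wcss_of <- function(durations, labels) {
  sum(vapply(split(durations, labels), function(g)
    sum((g - mean(g))^2), numeric(1)))
}

# Exact two-tailed binomial p by direct mass enumeration.
binom_two_tailed_brute <- function(k, n, p0) {
  pmf <- vapply(0:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
                numeric(1))
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-12)])
}

# Perpendicular (orthogonal) regression by numeric minimization of the sum
# of squared perpendicular distances.
deming_numeric_oracle <- function(x, y) {
  f <- function(par) {
    b <- par[1]; a <- par[2]
    sum((y - a - b * x)^2) / (1 + b^2)
  }
  ls <- stats::lm.fit(cbind(1, x), y)$coefficients
  o <- optim(c(ls[2], ls[1]), f, method = "BFGS",
             control = list(reltol = 1e-14))
  list(slope = o$par[1], intercept = o$par[2], sse = o$value)
}

perp_sse <- function(x, y, slope, intercept) {
  sum((y - intercept - slope * x)^2) / (1 + slope^2)
}

# Small helpers to build traces directly.
flat_sweep <- function(level = -75.1, fs = 20000, duration = 0.5,
                       stim_onset = 0.25) {
  sweep_trace(rep(level, duration * fs), fs, stim_onset)
}

# A sweep with a hand-planted voltage course (vector given in mV).
vm_sweep <- function(vm, fs = 20000, stim_onset = 0.1, i_command = 0) {
  sweep_trace(vm, fs, stim_onset, i_command = i_command)
}

stay_params <- function(condition = "none", gain_coef = 1.2) {
  p <- default_cell_params("P12-14", condition)
  p$psp_gain_mV <- setNames(gain_coef * p$depol_to_threshold_mV,
                            names(p$depol_to_threshold_mV))
  p
}
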