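# Extracellular unit classification and period-restricted rates.

test_that("bandpass_waveform removes DC, keeps the band, and is idempotent", {
  fs <- 30000
  dc <- rep(1, 300)
  expect_lt(max(abs(bandpass_waveform(dc, fs))), 0.05)
  t <- (0:299) / fs
  sine <- sin(2 * pi * 2000 * t)
  out <- bandpass_waveform(sine, fs)
  mid <- 100:200
  expect_lt(abs(max(abs(out[mid])) - 1), 0.05)
  # filtering twice leaves the trough-to-peak duration unchanged
  u <- simulate_units(n_units = 1, seed = 2)[[1]]
  once <- bandpass_waveform(u$mean_waveform, u$waveform_fs)
  twice <- bandpass_waveform(once, u$waveform_fs)
  expect_equal(trough_to_peak_ms(once, u$waveform_fs),
               trough_to_peak_ms(twice, u$waveform_fs))
})

test_that("trough_to_peak_ms is the trough-to-subsequent-peak time", {
  wf <- rep(0, 80)
  wf[30] <- -1
  wf[48] <- 0.5
  expect_equal(trough_to_peak_ms(wf, 30000), 18 / 30000 * 1000)
  expect_equal(trough_to_peak_ms(wf, 30000), 0.6)
  mono <- seq(1, 0, length.out = 50)
  out <- trough_to_peak_ms(mono, 30000)
  expect_true(is.na(out))
  expect_true(isTRUE(attr(out, "unassignable")))
})

test_that("split_two_classes equals the brute-force optimal 1-D partition", {
  sp <- split_two_classes(c(0.3, 0.35, 0.9, 1.0))
  expect_equal(as.character(sp$labels), c("narrow", "narrow", "wide", "wide"))
  set.seed(33)
  for (rep in 1:15) {
    n <- sample(5:200, 1)
    x <- c(rnorm(ceiling(n / 2), 0.35, 0.07), rnorm(floor(n / 2), 0.95, 0.15))
    x <- x[x > 0]
    sp <- split_two_classes(x)
    bf <- split2_brute(x)
    expect_equal(wcss_of(x, as.character(sp$labels)), bf$wcss,
                 tolerance = 1e-10)
  }
  expect_error(split_two_classes(rep(0.5, 5)), "identical")
})

test_that("planted mixtures are recovered with low label error", {
  # well-separated components; appreciable overlap raises the error floor
  units <- simulate_units(n_units = 300, seed = 9, sds = c(0.04, 0.08))
  durs <- vapply(units, function(u) u$ground_truth$duration_ms, numeric(1))
  truth <- vapply(units, function(u) u$ground_truth$class, character(1))
  sp <- split_two_classes(durs)
  expect_lt(mean(as.character(sp$labels) != truth), 0.02)
})

test_that("boundary durations go to the nearer mean, ties toward wide", {
  x <- c(0.4, 0.4, 0.8, 0.8, 0.6)    # 0.6 equidistant from both means
  sp <- split_two_classes(x)
  expect_equal(as.character(sp$labels)[5], "wide")
})

test_that("inclusion filter enforces spike count and coverage", {
  span <- c(0, 8100)
  u900 <- list(spike_times = seq(1, 8095, length.out = 900))
  expect_true(inclusion_filter(u900, span))
  u899 <- list(spike_times = seq(1, 8095, length.out = 899))
  expect_false(inclusion_filter(u899, span))
  u_half <- list(spike_times = runif(5000, 0, 4000))
  expect_false(inclusion_filter(u_half, span))
})

test_that("period rates equal an independent recount and are additive", {
  periods <- period_defs()
  set.seed(4)
  u <- list(spike_times = sort(runif(4000, 0, 8100)))
  r <- period_rates(u, periods)
  for (p in 1:3) {
    a <- periods$analysis_start_s[p]; b <- periods$end_s[p]
    expect_equal(r[[p]], sum(u$spike_times >= a & u$spike_times < b) / (b - a))
  }
  # splitting a window in half and averaging reproduces the full rate
  a <- periods$analysis_start_s[1]; b <- periods$end_s[1]; m <- (a + b) / 2
  r1 <- sum(u$spike_times >= a & u$spike_times < m) / (m - a)
  r2 <- sum(u$spike_times >= m & u$spike_times < b) / (b - m)
  expect_equal((r1 * (m - a) + r2 * (b - m)) / (b - a), r[[1]])
  expect_equal(period_rates(list(spike_times = numeric(0)), periods)[[1]], 0)
})

test_that("rate normalization maps baseline to one and flags zero baselines", {
  expect_equal(unname(normalize_rates(c(baseline = 4, fever = 6,
                                        recovery = 4))),
               c(1, 1.5, 1))
  out <- normalize_rates(c(baseline = 0, fever = 2, recovery = 1))
  expect_true(all(is.na(out)))
  expect_true(isTRUE(attr(out, "excluded")))
})

test_that("classify_units recovers the planted class structure end to end", {
  units <- simulate_units(n_units = 200, narrow_frac = 0.22, seed = 15,
                          sds = c(0.04, 0.08))
  tab <- classify_units(units, min_spikes = 50)
  truth <- vapply(units, function(u) u$ground_truth$class, character(1))
  inc <- tab$included
  expect_gt(mean(inc), 0.9)
  expect_lt(mean(tab$unit_class[inc] != truth[inc]), 0.02)
  # fever multiplier 1.4 shows up in the normalized rates
  ok <- inc & is.finite(tab$norm_fever)
  expect_equal(mean(tab$norm_fever[ok]), 1.4, tolerance = 0.1)
  expect_equal(median(tab$norm_baseline[ok]), 1)
})
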