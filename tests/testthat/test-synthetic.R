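# The synthetic generators: determinism, ground-truth realizability, and
# the stated construction identities.

test_that("evoked sweep generator honours its trivial limits", {
  p <- stay_params()
  # no drive, no noise: flat at baseline, no spikes
  s0 <- simulate_sweep(p, 36, noise_sd = 0, psp_gain = 0, seed = 1)
  p0 <- p; p0$ipsp_gain_mV[] <- 0
  s0 <- simulate_sweep(p0, 36, noise_sd = 0, psp_gain = 0, seed = 1)
  expect_true(all(s0$vm == p$base_level_mV))
  expect_equal(nrow(detect_spikes(s0)), 0)
  # strong drive: exactly one inserted spike taking off at threshold
  s1 <- simulate_sweep(p, 36, noise_sd = 0, seed = 1)
  ev <- detect_spikes(s1)
  expect_gte(nrow(ev), 1)
  st_true <- p$base_level_mV + p$depol_to_threshold_mV[["36"]]
  expect_lt(abs(ev$v_threshold[1] - st_true), 0.5)  # within one sample's rise
  expect_equal(ev$v_peak[1], p$base_level_mV + p$spike_height_mV,
               tolerance = 0.01)
})

test_that("generators are deterministic under a fixed seed", {
  p <- stay_params()
  a <- simulate_sweep(p, 39, seed = 42)
  b <- simulate_sweep(p, 39, seed = 42)
  expect_identical(a$vm, b$vm)
  cfg <- sim_config(seed = 5, n_cells = 2, include_steps = FALSE)
  expect_identical(simulate_cell_population(cfg),
                   simulate_cell_population(cfg))
  expect_identical(simulate_units(n_units = 10, seed = 3),
                   simulate_units(n_units = 10, seed = 3))
  t1 <- simulate_tb(seed = 4, noise_sd = 0.2)
  t2 <- simulate_tb(seed = 4, noise_sd = 0.2)
  expect_identical(t1$temp_C, t2$temp_C)
})

test_that("simulation parameters are validated", {
  p <- stay_params()
  p$psp_gain_mV[["36"]] <- NaN
  expect_error(simulate_sweep(p, 36), "non-finite")
  expect_error(sim_config(fate_fractions = c(never = 0.5, stop = 0.5,
                                             stay = 0.5, start = -0.5)),
               "sum to 1|non-negative")
  expect_error(sim_config(condition = "trpv3_block",
                          fate_fractions = c(never = 0, stop = 0,
                                             stay = 0.5, start = 0.5)),
               "START")
  expect_error(sim_config(stim_onset = 0.6), "stim_onset")
})

test_that("step protocol obeys Ohm's law and brute-force rheobase", {
  p <- default_cell_params()
  p$rin_MOhm[] <- 100
  sw <- simulate_step_protocol(p, 36, amplitudes = -50, noise_sd = 0)[[1]]
  idx <- thermofate:::window_idx(sw, c(0.55, 0.6))   # late in the step
  expect_equal(mean(sw$vm[idx]) - (-80), -5, tolerance = 0.01)

  # grid straddling the rheobase: first spiking step equals the exhaustive
  # minimum over the grid, and sub-rheobase steps never spike
  p2 <- default_cell_params()
  amps <- seq(25, 300, by = 25)
  steps <- simulate_step_protocol(p2, 30, amplitudes = amps, noise_sd = 0)
  counts <- vapply(steps, thermofate:::step_spike_count, numeric(1))
  st <- p2$base_level_mV + p2$depol_to_threshold_mV[["30"]]
  need <- (st + 80) / (p2$rin_MOhm[["30"]] * 1e-3)
  expect_true(all(counts[amps < need] == 0))
  first_spiking <- amps[which(counts > 0)[1]]
  expect_equal(first_spiking, min(amps[amps * p2$rin_MOhm[["30"]] * 1e-3 - 80 > st]))
  expect_error(simulate_step_protocol(p2, 30, amplitudes = c(100, 50)),
               "ascending")
  expect_error(simulate_step_protocol(p2, 30, amplitudes = 50, duration = 0),
               "positive")
})

test_that("intended fates are realized by construction", {
  mix <- c(never = 0.25, stop = 0.25, stay = 0.25, start = 0.25)
  for (noise in c(0, 0.3)) {
    cfg <- sim_config(seed = 21, n_cells = 16, noise_sd = noise,
                      fate_fractions = mix, include_steps = FALSE)
    pop <- simulate_cell_population(cfg)
    fx <- extract_features(pop)
    f3 <- classify_fates(fx, "three_temp")
    intended <- vapply(pop, function(cl) cl$intended_fate, character(1))
    agree <- mean(f3$label == intended)
    if (noise == 0) expect_equal(agree, 1) else expect_gte(agree, 0.95)
  }
  # all-STAY cohort spikes at every temperature
  cfg <- sim_config(seed = 3, n_cells = 4, noise_sd = 0,
                    fate_fractions = c(never = 0, stop = 0, stay = 1,
                                       start = 0), include_steps = FALSE)
  fx <- extract_features(simulate_cell_population(cfg))
  expect_true(all(fx$n_spiking_sweeps > 0))
})

test_that("fate fractions are realized at cohort scale", {
  cfg <- sim_config(seed = 14, n_cells = 37, noise_sd = 0,
                    fate_fractions = c(never = 0.43, stop = 0.15,
                                       stay = 0.27, start = 0.15),
                    include_steps = FALSE)
  pop <- simulate_cell_population(cfg)
  n_stay <- sum(vapply(pop, function(cl) cl$intended_fate, character(1)) == "STAY")
  # expected 0.27 * 37 = 10; allow 3 binomial SDs
  expect_lt(abs(n_stay - 10), 3 * sqrt(37 * 0.27 * 0.73) + 1)
})

test_that("unit generator realizes the duration mixture and rate structure", {
  units <- simulate_units(n_units = 633, narrow_frac = 0.22, seed = 17)
  cls <- vapply(units, function(u) u$ground_truth$class, character(1))
  # expected narrow count 0.22 * 633 = 139; binomial noise
  expect_lt(abs(sum(cls == "narrow") - 139), 3 * sqrt(633 * 0.22 * 0.78))
  # waveform trough-to-peak equals the drawn duration within one sample
  for (u in units[1:25]) {
    d <- trough_to_peak_ms(u$mean_waveform, u$waveform_fs)
    expect_lt(abs(d - u$ground_truth$duration_ms), 1000 / u$waveform_fs + 1e-9)
  }
  # flat multipliers give equal period rates within Poisson error
  units_flat <- simulate_units(n_units = 50, seed = 5,
                               rate_multipliers = list(narrow = c(1, 1, 1),
                                                       wide = c(1, 1, 1)))
  periods <- attr(units_flat, "periods")
  for (u in units_flat[1:10]) {
    r <- period_rates(u, periods)
    se <- 3 * sqrt(r[["baseline"]] / (25 * 60))
    expect_lt(abs(r[["fever"]] - r[["baseline"]]), 3 * se + 0.05)
  }
})

test_that("telemetry generator plants what the detector must find", {
  tb <- simulate_tb(seed = 1, noise_sd = 0)
  s <- summarize_tb(tb)
  expect_equal(s$median_C, 36.5)
  expect_equal(s$max_fluctuation_C, 0)
  expect_equal(s$min_fluctuation_C, 0)
  # heating ramp 36 -> 39 degC in 300 s recovers 0.01 degC/s
  tbr <- simulate_tb(seed = 1, noise_sd = 0, baseline = 36,
                     ramp = list(t0 = 3600, rate = 0.01, target = 39))
  expect_equal(heating_rate(tbr, 3600, 3900), 0.01, tolerance = 1e-9)
  # one planted excursion above threshold -> exactly one episode
  tbe <- simulate_tb(seed = 1, noise_sd = 0,
                     excursions = data.frame(onset_s = 7000, peak_C = 38.9,
                                             duration_s = 1500))
  ep <- detect_fever_episodes(tbe, 38)
  expect_equal(nrow(ep), 1)
  expect_error(simulate_tb(interval_min = 0), "positive")
})
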