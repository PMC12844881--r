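# Trace feature extraction: resting potential, spike detection and
# threshold, PSP quantification, input resistance, rheobase, F-I.

test_that("estimate_rmp is the pre-stimulus mean and validates its window", {
  s <- flat_sweep(-75.1)
  expect_equal(estimate_rmp(s), -75.1)
  expect_error(estimate_rmp(s, pre_window = c(0.3, 0.4)), "overlaps")
  # planted resting level + zero-mean noise recovers within 0.1 mV
  set.seed(2)
  vm <- -74.4 + thermofate:::filtered_noise(10000, 20000, 0.3)
  s2 <- vm_sweep(vm, stim_onset = 0.5)
  expect_lt(abs(estimate_rmp(s2, c(0.3, 0.4)) - (-74.4)), 0.1)
})

test_that("detect_spikes finds inserted spikes and nothing else", {
  p <- stay_params()
  sub <- simulate_sweep(p, 36, noise_sd = 0.3, psp_gain = 2, seed = 4)
  expect_equal(nrow(detect_spikes(sub)), 0)
  s1 <- simulate_sweep(p, 36, noise_sd = 0, seed = 1)
  ev <- detect_spikes(s1)
  expect_equal(ev$v_peak[1], p$base_level_mV + p$spike_height_mV,
               tolerance = 0.01)
  # two hand-planted spikes 50 ms apart come back in time order
  vm <- rep(-50, 10000)
  vm <- thermofate:::insert_spike(vm, 3000, 20000, v_peak = 10, v_ahp = -55)
  vm <- thermofate:::insert_spike(vm, 4000, 20000, v_peak = 10, v_ahp = -55)
  ev2 <- detect_spikes(vm_sweep(vm))
  expect_equal(nrow(ev2), 2)
  expect_true(ev2$t_peak[1] < ev2$t_peak[2])
  # a window opening mid-spike does not fabricate an event
  ev3 <- detect_spikes(vm_sweep(vm), window = c(3005 / 20000, 0.4))
  expect_equal(nrow(ev3), 1)
})

test_that("second-derivative threshold recovers the generative take-off", {
  p <- stay_params()
  for (tl in c("30", "36", "39")) {
    s <- simulate_sweep(p, as.numeric(tl), noise_sd = 0, seed = 1)
    ev <- detect_spikes(s, c(s$stim_onset, 0.5))
    st_hat <- estimate_spike_threshold(s, ev[1, ])
    st_true <- p$base_level_mV + p$depol_to_threshold_mV[[tl]]
    expect_lt(abs(st_hat - st_true), 0.5)
  }
})

test_that("threshold estimate is translation-equivariant and fails on ramps", {
  p <- stay_params()
  s <- simulate_sweep(p, 39, noise_sd = 0.3, seed = 6)
  ev <- detect_spikes(s, c(s$stim_onset, 0.5))
  st1 <- estimate_spike_threshold(s, ev[1, ])
  s7 <- s; s7$vm <- s$vm + 7
  ev7 <- detect_spikes(s7, c(s$stim_onset, 0.5))
  st2 <- estimate_spike_threshold(s7, ev7[1, ])
  expect_equal(st2, st1 + 7)
  expect_equal(depolarization_to_threshold(st2, thermofate:::baseline_of(s7)),
               depolarization_to_threshold(st1, thermofate:::baseline_of(s)))
  # a pure linear ramp has no inflection: estimate flagged as failed
  set.seed(3)
  vm <- -60 + 0.002 * (1:10000) + thermofate:::filtered_noise(10000, 20000, 0.2)
  sr <- vm_sweep(vm)
  fake <- data.frame(i_peak = 9000)
  out <- estimate_spike_threshold(sr, fake)
  expect_true(is.na(out))
  expect_true(isTRUE(attr(out, "estimate_failed")))
})

test_that("depolarization_to_threshold arithmetic", {
  expect_equal(depolarization_to_threshold(-43, -50), 7)
  expect_equal(depolarization_to_threshold(-50, -50), 0)
  expect_true(is.na(depolarization_to_threshold(NA, -50)))
})

test_that("psp_peak and late_psp quantify deflections from baseline", {
  # crafted trace: baseline -50, peak -44.5 in the window
  vm <- rep(-50, 10000)
  vm[2200:2400] <- -44.5
  expect_equal(psp_peak(list(vm_sweep(vm))), 5.5)
  # all-flat sweeps give zero
  expect_equal(psp_peak(list(flat_sweep(-50, stim_onset = 0.1))), 0)
  # noiseless simulated subthreshold PSP of 3 mV
  p <- stay_params()
  s <- simulate_sweep(p, 36, noise_sd = 0, psp_gain = 3, seed = 1)
  expect_equal(psp_peak(list(s)), 3, tolerance = 0.05)
  # planted -2 mV plateau across the late window
  vm2 <- rep(-50, 10000)
  vm2[thermofate:::window_idx(vm_sweep(vm2), c(0.15, 0.2))] <- -52
  expect_equal(late_psp(list(vm_sweep(vm2))), -2, tolerance = 0.05)
  # no inhibition and a fully decayed PSP: late component is zero
  p0 <- stay_params(); p0$ipsp_gain_mV[] <- 0; p0$psp_decay_ms <- 5
  s0 <- simulate_sweep(p0, 36, noise_sd = 0, psp_gain = 2, seed = 1)
  expect_equal(late_psp(list(s0)), 0, tolerance = 0.05)
})

test_that("estimated late PSP magnitude tracks the generative inhibition", {
  p <- stay_params()
  vals <- vapply(c("30", "36", "39"), function(tl) {
    late_psp(list(simulate_sweep(p, as.numeric(tl), noise_sd = 0,
                                 psp_gain = 2, seed = 1)))
  }, numeric(1))
  # generative ipsp gain decreases 30 -> 39, so the measured late component
  # becomes strictly less negative
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < 0))
})

test_that("input_resistance implements Ohm's law on the step steady state", {
  p <- default_cell_params()
  p$rin_MOhm[] <- 150
  sw <- simulate_step_protocol(p, 36, amplitudes = -50, noise_sd = 0.3,
                               seed = 2)[[1]]
  expect_equal(input_resistance(sw), 150, tolerance = 0.01)
  expect_error(input_resistance(flat_sweep()), "step_window required")
  sw0 <- sw; sw0$i_command <- rep(0, length(sw0$vm))
  expect_error(input_resistance(sw0), "no current step")
  expect_error(input_resistance(sw, delta_i = 0,
                                step_window = c(0.1, 0.6)), "nonzero")
  # spiking sweeps are rejected
  swp <- simulate_step_protocol(p, 36, amplitudes = 400, noise_sd = 0)[[1]]
  expect_error(input_resistance(swp, delta_i = 400,
                                step_window = c(0.1, 0.6)), "rejected")
})

test_that("rheobase equals the grid scan and flags the no-spike case", {
  p <- default_cell_params()
  amps <- seq(50, 450, by = 50)
  steps <- simulate_step_protocol(p, 36, amplitudes = amps, noise_sd = 0)
  rb <- rheobase(steps)
  counts <- vapply(steps, thermofate:::step_spike_count, numeric(1))
  expect_equal(rb, amps[which(counts >= 1)[1]])
  low <- simulate_step_protocol(p, 36, amplitudes = c(10, 20), noise_sd = 0)
  out <- rheobase(low)
  expect_true(is.na(out))
  expect_true(isTRUE(attr(out, "undefined")))
})

test_that("fi_curve is monotone on noiseless data and keeps duplicates", {
  p <- default_cell_params()
  amps <- seq(100, 600, by = 100)
  steps <- simulate_step_protocol(p, 39, amplitudes = amps, noise_sd = 0)
  fi <- fi_curve(steps)
  expect_true(all(diff(fi$n_spikes) >= 0))
  dup <- simulate_step_protocol(p, 39, amplitudes = c(100, 100), noise_sd = 0)
  fi2 <- fi_curve(dup)
  expect_equal(nrow(fi2), 2)
  expect_equal(fi2$amplitude_pA, c(100, 100))
})

test_that("mean_evoked_spikes equals an independent recount", {
  p <- stay_params()
  sweeps <- lapply(1:6, function(k)
    simulate_sweep(p, 39, noise_sd = 0.3, seed = k))
  m <- mean_evoked_spikes(sweeps)
  recount <- mean(vapply(sweeps, function(s) {
    w <- s$stim_onset + c(0.0025, 0.1525)
    nrow(detect_spikes(s, w))
  }, numeric(1)))
  expect_equal(m, recount)
  flat <- lapply(1:3, function(k) flat_sweep(-50))
  expect_equal(mean_evoked_spikes(flat), 0)
})

test_that("net_iv subtracts matched voltage grids element-wise", {
  a <- data.frame(voltage_mV = c(-80, 80), density_pA_pF = c(5, 10))
  b <- data.frame(voltage_mV = c(-80, 80), density_pA_pF = c(2, 4))
  expect_equal(net_iv(a, b)$density_pA_pF, c(3, 6))
  expect_equal(net_iv(a, a)$density_pA_pF, c(0, 0))
  expect_error(net_iv(a, b[1, , drop = FALSE]), "match")
})

test_that("features are stable under resampling of a noiseless sweep", {
  p <- stay_params()
  f_at <- function(fs) {
    s <- simulate_sweep(p, 39, noise_sd = 0, fs = fs, seed = 1)
    ev <- detect_spikes(s, c(s$stim_onset, 0.5))
    st <- estimate_spike_threshold(s, ev[1, ])
    c(st = st,
      depol = depolarization_to_threshold(st, thermofate:::baseline_of(s)))
  }
  f20 <- f_at(20000)
  f40 <- f_at(40000)
  expect_lt(abs(f40[["depol"]] - f20[["depol"]]) / abs(f20[["depol"]]), 0.01)
  expect_lt(abs(f40[["st"]] - f20[["st"]]) / abs(f20[["st"]]), 0.01)
})

test_that("estimators recover generative parameters across a noiseless cohort", {
  cfg <- sim_config(seed = 31, n_cells = 40, noise_sd = 0,
                    fate_fractions = c(never = 0, stop = 0, stay = 1,
                                       start = 0),
                    step_amplitudes = c(-50, 100, 200, 300),
                    include_steps = TRUE)
  pop <- simulate_cell_population(cfg)
  fx <- extract_features(pop)
  gt <- do.call(rbind, lapply(pop, function(cl) data.frame(
    cell_id = cl$cell_id,
    temperature = as.numeric(names(cl$ground_truth$rmp_mV)),
    rmp_true = unname(cl$ground_truth$rmp_mV),
    depol_true = unname(cl$ground_truth$depol_to_threshold_mV),
    rin_true = unname(cl$ground_truth$rin_MOhm),
    rheo_true = unname(cl$ground_truth$rheobase_pA))))
  m <- merge(fx, gt)
  expect_true(all(abs(m$rmp - m$rmp_true) < 0.5))
  expect_true(all(abs(m$depol_to_threshold - m$depol_true) < 0.5))
  expect_true(all(abs(m$rin / m$rin_true - 1) < 0.02))
  same_rheo <- is.na(m$rheobase) == is.na(m$rheo_true) &
    (is.na(m$rheobase) | m$rheobase == m$rheo_true)
  expect_true(all(same_rheo))
})
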