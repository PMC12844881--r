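# Synthetic-data generators: current-clamp sweeps with temperature-dependent
# spike threshold / input resistance / PSP structure, extracellular units with
# bimodal spike durations and period-modulated Poisson trains, and body-
# temperature telemetry.  Every generator is deterministic given its seed and
# carries ground-truth labels so the analysis stages can be tested end to end.

#' Default generative cell parameters
#'
#' Per-temperature generative parameters for a simulated layer 2/3 pyramidal
#' neuron.  Temperatures are labelled 30, 36 and 39 (degrees C).  The maps
#' encode the temperature structure the analysis is designed to detect:
#' spike threshold depolarises with temperature, input resistance falls,
#' the late (inhibitory) PSP component shrinks, and pharmacological TRPV3
#' block / knockout hyperpolarises the resting potential by about 3 mV and
#' changes the depolarization-to-threshold map.
#'
#' @param age_group one of `"P7-8"`, `"P12-14"`, `"P20-23"`.
#' @param condition one of `"none"`, `"wt"`, `"trpv3_block"`, `"trpv4_block"`,
#'   `"trpv3_ko"`.
#' @return a list of per-temperature named vectors and scalar kernel
#'   parameters (class `"cell_params"`).
#' @export
default_cell_params <- function(age_group = "P12-14", condition = "none") {
  age_group <- match.arg(age_group, c("P7-8", "P12-14", "P20-23"))
  condition <- match.arg(condition,
                         c("none", "wt", "trpv3_block", "trpv4_block", "trpv3_ko"))
  temps <- c("30", "36", "39")
  blockish <- condition %in% c("trpv3_block", "trpv3_ko")
  rmp <- if (blockish) c(-77.1, -76.3, -74.4) else c(-75.1, -73.5, -71.3)
  depol <- if (blockish) c(7.15, 8.39, 10.0) else c(6.0, 8.2, 10.4)
  if (age_group == "P7-8") depol <- c(6.5, 8.5, 8.6)  # threshold plateaus 36->39
  ipsp <- if (blockish) c(2.0, 1.9, 1.8) else c(2.0, 1.5, 1.0)
  p <- list(
    temperatures = c(30, 36, 39),
    rmp_mV = setNames(rmp, temps),
    depol_to_threshold_mV = setNames(depol, temps),
    rin_MOhm = setNames(c(150, 120, 100), temps),
    ipsp_gain_mV = setNames(ipsp, temps),
    base_level_mV = -50,          # evoked-protocol pre-stimulus baseline
    psp_onset_ms = 3,             # monosynaptic latency after the stimulus
    psp_rise_ms = 2, psp_decay_ms = 20,
    ipsp_onset_ms = 15, ipsp_rise_ms = 5, ipsp_decay_ms = 50,
    spike_height_mV = 60,         # peak above the sweep baseline
    ahp_mV = 10,                  # undershoot below threshold
    membrane_tau_ms = 20,
    age_group = age_group, condition = condition
  )
  class(p) <- "cell_params"
  p
}

#' Simulation configuration
#'
#' Bundles every knob of the intracellular simulation: protocol geometry,
#' stimulus strength (as a multiple of the unit synaptic drive, the analogue
#' of stimulating at 1.4 times the minimal effective intensity), noise level
#' and the intended thermal-fate mix of the population.
#'
#' @param seed integer seed; all randomness of the population flows from it.
#' @param n_cells number of cells to simulate.
#' @param age_group,condition passed to [default_cell_params()].
#' @param fs sampling rate in Hz.
#' @param sweep_duration sweep length in seconds.
#' @param stim_onset stimulus time in seconds.
#' @param n_sweeps_per_temp evoked sweeps per temperature (protocol default 11).
#' @param temperatures ordered temperature labels in degrees C.
#' @param stim_strength stimulus strength as a multiple of unit drive;
#'   the generative PSP gains are calibrated at 1.4.
#' @param noise_sd SD (mV) of the low-pass-filtered Gaussian recording noise.
#' @param fate_fractions named fractions (never/stop/stay/start) summing to 1.
#' @param step_amplitudes current-step protocol amplitudes in pA; must include
#'   -50 pA (the input-resistance step).
#' @param include_steps logical; generate the step protocol (default TRUE).
#' @param params generative parameter maps, default [default_cell_params()].
#' @param cell_sd_depol,cell_sd_rmp,cell_sd_log_rin between-cell SDs of the
#'   threshold-depolarization offset (mV), resting-potential offset (mV) and
#'   log input resistance.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_cells = 20L,
                       age_group = "P12-14", condition = "none",
                       fs = 20000, sweep_duration = 0.5, stim_onset = 0.1,
                       n_sweeps_per_temp = 11L, temperatures = c(30, 36, 39),
                       stim_strength = 1.4, noise_sd = 0.3,
                       fate_fractions = c(never = 0.32, stop = 0.22,
                                          stay = 0.27, start = 0.19),
                       step_amplitudes = c(-50, seq(25, 250, by = 25)),
                       include_steps = TRUE,
                       params = default_cell_params(age_group, condition),
                       cell_sd_depol = 1.0, cell_sd_rmp = 1.5,
                       cell_sd_log_rin = 0.12) {
  stopifnot(fs > 0, stim_onset >= 0, stim_onset < sweep_duration,
            n_sweeps_per_temp >= 1, n_cells >= 0, noise_sd >= 0,
            stim_strength > 0)
  nm <- sort(names(fate_fractions))
  if (!identical(nm, c("never", "start", "stay", "stop")))
    stop("fate_fractions must be named never/stop/stay/start")
  if (abs(sum(fate_fractions) - 1) > 1e-9)
    stop("fate_fractions must sum to 1")
  if (any(fate_fractions < 0)) stop("fate_fractions must be non-negative")
  blockish <- params$condition %in% c("trpv3_block", "trpv3_ko")
  if (blockish && fate_fractions[["start"]] > 0)
    stop("a flat PSP gain (TRPV3 block/knockout) cannot realize START fates")
  if (include_steps && !(-50 %in% step_amplitudes))
    stop("step_amplitudes must include the -50 pA input-resistance step")
  cfg <- list(seed = as.integer(seed), n_cells = as.integer(n_cells),
              age_group = age_group, condition = condition, fs = fs,
              sweep_duration = sweep_duration, stim_onset = stim_onset,
              n_sweeps_per_temp = as.integer(n_sweeps_per_temp),
              temperatures = temperatures, stim_strength = stim_strength,
              noise_sd = noise_sd, fate_fractions = fate_fractions,
              step_amplitudes = step_amplitudes, include_steps = include_steps,
              params = params, cell_sd_depol = cell_sd_depol,
              cell_sd_rmp = cell_sd_rmp, cell_sd_log_rin = cell_sd_log_rin)
  class(cfg) <- "sim_config"
  cfg
}

#' Construct a current-clamp sweep object
#'
#' @param vm membrane potential samples in mV.
#' @param fs sampling rate in Hz.
#' @param stim_onset stimulus time in seconds (set to the sweep duration for
#'   unstimulated sweeps).
#' @param i_command command current in pA (scalar, or per-sample vector).
#' @param temperature temperature label in degrees C.
#' @param sweep_index integer index within its protocol.
#' @return a list of class `"sweep_trace"`.
#' @export
sweep_trace <- function(vm, fs, stim_onset, i_command = 0,
                        temperature = NA_real_, sweep_index = 1L) {
  if (!all(is.finite(vm))) stop("vm samples must all be finite")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  dur <- length(vm) / fs
  if (stim_onset < 0 || stim_onset > dur)
    stop("stim_onset must lie within [0, duration]")
  structure(list(vm = as.numeric(vm), fs = fs, stim_onset = stim_onset,
                 i_command = i_command, temperature = temperature,
                 sweep_index = as.integer(sweep_index)),
            class = "sweep_trace")
}

# Low-pass-filtered Gaussian noise rescaled to an exact SD.
filtered_noise <- function(n, fs, sd_mV, cutoff_hz = 1000) {
  if (sd_mV <= 0) return(numeric(n))
  w <- rnorm(n)
  bf <- signal::butter(2, min(0.99, cutoff_hz / (fs / 2)), type = "low")
  f <- signal::filtfilt(bf, w)
  f / stats::sd(f) * sd_mV
}

# Difference-of-exponentials kernel with unit peak, evaluated at t (s) >= 0.
psp_kernel <- function(t, rise_ms, decay_ms) {
  tr <- rise_ms / 1000
  td <- decay_ms / 1000
  k <- exp(-t / td) - exp(-t / tr)
  tpk <- log(td / tr) * tr * td / (td - tr)
  k / (exp(-tpk / td) - exp(-tpk / tr))
}

# Stereotyped action potential pasted onto a subthreshold trajectory starting
# at index i0 (the take-off sample).  Returns the modified vm.  The take-off
# Vm equals the trajectory value at i0; rise and fall are cosine ramps so the
# upstroke slope comfortably exceeds the 20 mV/ms detection criterion.
insert_spike <- function(vm, i0, fs, v_peak, v_ahp, tau_rec_ms = 8,
                         rise_ms = 0.3, fall_ms = 1.2) {
  n <- length(vm)
  nr <- max(2L, round(rise_ms / 1000 * fs))
  nf <- max(2L, round(fall_ms / 1000 * fs))
  v0 <- vm[i0]
  iri <- i0 + seq_len(nr)
  iri <- iri[iri <= n]
  vm[iri] <- v0 + (v_peak - v0) * (1 - cos(pi * seq_along(iri) / nr)) / 2
  ifa <- i0 + nr + seq_len(nf)
  ifa <- ifa[ifa <= n]
  vm[ifa] <- v_peak + (v_ahp - v_peak) * (1 - cos(pi * seq_along(ifa) / nf)) / 2
  itr <- i0 + nr + nf          # AHP trough index
  if (itr < n) {
    idx <- (itr + 1L):n
    off <- (v_ahp - vm[itr + 1L]) * exp(-(idx - itr) / fs / (tau_rec_ms / 1000))
    vm[idx] <- vm[idx] + off
  }
  vm
}

# PSP gain (mV at 1.4x drive) realizing an intended fate, given the cell's own
# per-temperature depolarization-to-threshold.  STAY gains track the threshold
# (the excitation/threshold coupling); STOP gains are flat; START gains grow
# with temperature; block/knockout conditions force flat gains throughout.
fate_psp_gain <- function(fate, depol, flat = FALSE) {
  if (flat) {
    g <- switch(fate,
                NEVER = 0.6 * depol[1],
                STOP  = depol[1] + 0.3,
                STAY  = 1.15 * depol[length(depol)],
                START = stop("flat PSP gain cannot realize START"))
    return(rep(g, length(depol)))
  }
  switch(fate,
         NEVER = 0.6 * depol,
         STOP  = rep(depol[1] + 0.3, length(depol)),
         STAY  = 1.2 * depol,
         START = c(0.7, 0.9, 1.2)[seq_along(depol)] * depol)
}

#' Simulate one evoked-PSP current-clamp sweep
#'
#' The subthreshold trajectory is the baseline plus an excitatory
#' difference-of-exponentials PSP and a delayed inhibitory component, plus
#' low-pass-filtered Gaussian noise.  Whenever the deterministic trajectory
#' crosses the temperature-specific spike threshold a stereotyped action
#' potential (rise to peak, repolarization, afterhyperpolarization) is pasted
#' in; spike initiation is driven by the deterministic drive so that
#' ground-truth fate labels are exact, while the noise perturbs every
#' measured feature.
#'
#' @param params a `"cell_params"` list (see [default_cell_params()]), with
#'   elements `psp_gain_mV` (named per-temperature vector) added by the
#'   population generator, or supplied via `psp_gain`.
#' @param temperature temperature label (must appear in the parameter maps).
#' @param stim_strength stimulus strength, multiple of unit drive.
#' @param noise_sd noise SD in mV.
#' @param seed optional integer seed.
#' @param fs,duration,stim_onset protocol geometry.
#' @param psp_gain optional override of the excitatory PSP amplitude (mV).
#' @param base_level optional override of the pre-stimulus baseline (mV).
#' @param refractory_ms minimal spacing of generated spikes.
#' @param sweep_index index stored in the trace.
#' @return a [sweep_trace()].
#' @export
simulate_sweep <- function(params, temperature, stim_strength = 1.4,
                           noise_sd = 0.3, seed = NULL, fs = 20000,
                           duration = 0.5, stim_onset = 0.1,
                           psp_gain = NULL, base_level = NULL,
                           refractory_ms = 10, sweep_index = 1L) {
  tl <- as.character(temperature)
  depol <- params$depol_to_threshold_mV[[tl]]
  if (is.null(depol) || !is.finite(depol))
    stop("no finite parameters for temperature ", temperature)
  if (is.null(psp_gain)) psp_gain <- params$psp_gain_mV[[tl]]
  if (is.null(psp_gain)) stop("psp_gain not supplied and not in params")
  base <- if (is.null(base_level)) params$base_level_mV else base_level
  for (v in c(psp_gain, base, noise_sd, stim_strength))
    if (!is.finite(v)) stop("non-finite simulation parameter")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  eon <- stim_onset + params$psp_onset_ms / 1000
  post <- tt >= eon
  te <- tt[post] - eon
  drive <- numeric(n)
  gain_eff <- psp_gain * stim_strength / 1.4
  drive[post] <- gain_eff * psp_kernel(te, params$psp_rise_ms, params$psp_decay_ms)
  ipg <- params$ipsp_gain_mV[[tl]]
  ion <- params$ipsp_onset_ms / 1000
  late <- tt >= stim_onset + ion
  drive[late] <- drive[late] -
    ipg * psp_kernel(tt[late] - stim_onset - ion,
                     params$ipsp_rise_ms, params$ipsp_decay_ms)
  v_sub <- base + drive
  st <- base + depol
  vm <- v_sub
  # upward crossings from below: every take-off sits exactly at threshold
  up <- which(v_sub >= st & c(-Inf, v_sub[-n]) < st & post)
  nref <- max(1L, round(refractory_ms / 1000 * fs))
  last <- -Inf
  for (i0 in up) {
    if (i0 - last < nref) next
    vm <- insert_spike(vm, i0, fs,
                       v_peak = base + params$spike_height_mV,
                       v_ahp = st - params$ahp_mV)
    last <- i0
  }
  vm <- vm + filtered_noise(n, fs, noise_sd)
  sweep_trace(vm, fs, stim_onset, i_command = 0, temperature = temperature,
              sweep_index = sweep_index)
}

#' Simulate a current-step protocol
#'
#' Passive RC responses from a holding potential with integrate-and-fire
#' spiking: the membrane relaxes exponentially towards
#' `holding + I * R_in` (millivolts, with I in pA and R_in in megaohms);
#' when the trajectory reaches the temperature-specific spike threshold a
#' stereotyped spike is pasted in and the membrane restarts from the
#' afterhyperpolarization level.  Crossing times are computed in closed form,
#' so the ground-truth rheobase is exactly the smallest amplitude whose
#' steady state exceeds threshold.
#'
#' @param params a `"cell_params"` list; `rin_MOhm`, `depol_to_threshold_mV`,
#'   `base_level_mV` and `membrane_tau_ms` are used.
#' @param temperature temperature label.
#' @param amplitudes step amplitudes in pA, sorted ascending.
#' @param duration step duration in seconds (protocol default 0.5).
#' @param holding holding potential in mV (protocol default -80).
#' @param fs sampling rate (Hz).
#' @param noise_sd noise SD (mV).
#' @param seed optional seed.
#' @param pre_s,post_s pre- and post-step padding in seconds.
#' @return a list of [sweep_trace()] objects, one per amplitude; each carries
#'   its amplitude in `i_command`.
#' @export
simulate_step_protocol <- function(params, temperature, amplitudes,
                                   duration = 0.5, holding = -80, fs = 20000,
                                   noise_sd = 0.3, seed = NULL,
                                   pre_s = 0.1, post_s = 0.1) {
  if (duration <= 0) stop("duration must be positive")
  if (is.unsorted(amplitudes, strictly = FALSE))
    stop("amplitudes must be sorted ascending")
  if (!is.null(seed)) set.seed(seed)
  tl <- as.character(temperature)
  rin <- params$rin_MOhm[[tl]]
  st <- params$base_level_mV + params$depol_to_threshold_mV[[tl]]
  tau <- params$membrane_tau_ms / 1000
  n_pre <- round(pre_s * fs)
  n_step <- round(duration * fs)
  n_post <- round(post_s * fs)
  n <- n_pre + n_step + n_post
  lapply(seq_along(amplitudes), function(k) {
    I <- amplitudes[k]
    v_inf <- holding + I * rin * 1e-3          # pA * MOhm = microvolt = 1e-3 mV
    vm <- rep(holding, n)
    seg <- holding + (v_inf - holding) * (1 - exp(-(seq_len(n_step) / fs) / tau))
    spike_dur_s <- 2.0 / 1000                  # rise + fall of the stereotype
    if (v_inf > st) {
      # iterate closed-form crossings within the step
      t0 <- 0; v0 <- holding; spikes_at <- numeric(0)
      while (TRUE) {
        tc <- t0 - tau * log((v_inf - st) / (v_inf - v0))
        if (!is.finite(tc) || tc >= duration) break
        spikes_at <- c(spikes_at, tc)
        t0 <- tc + spike_dur_s
        v0 <- st - params$ahp_mV
        if (t0 >= duration) break
        idx <- which(seq_len(n_step) / fs > t0)
        seg[idx] <- v_inf + (v0 - v_inf) * exp(-(idx / fs - t0) / tau)
      }
      vm <- c(rep(holding, n_pre), seg,
              holding + (seg[n_step] - holding) * exp(-(seq_len(n_post) / fs) / tau))
      for (tc in spikes_at)
        vm <- insert_spike(vm, n_pre + max(1L, round(tc * fs)), fs,
                           v_peak = holding + params$spike_height_mV + 30,
                           v_ahp = st - params$ahp_mV)
    } else {
      vm <- c(rep(holding, n_pre), seg,
              holding + (seg[n_step] - holding) * exp(-(seq_len(n_post) / fs) / tau))
    }
    vm <- vm + filtered_noise(n, fs, noise_sd)
    i_cmd <- c(rep(0, n_pre), rep(I, n_step), rep(0, n_post))
    sweep_trace(vm, fs, stim_onset = pre_s, i_command = i_cmd,
                temperature = temperature, sweep_index = k)
  })
}

#' Simulate a population of cells with intended thermal fates
#'
#' Draws per-cell offsets around the generative parameter maps, assigns each
#' cell an intended fate (NEVER/STOP/STAY/START) from the configured
#' fractions, sets its PSP gain so the fate is realized by construction, and
#' generates the full protocol per temperature: evoked sweeps, an
#' unstimulated resting sweep (for the resting-potential measurement), and
#' optionally the current-step protocol.
#'
#' @param cfg a [sim_config()].
#' @return a list of cell records (class `"cell_population"`); each cell is a
#'   list with `cell_id`, `intended_fate`, `ground_truth` (per-temperature
#'   true RMP, threshold, depolarization-to-threshold, input resistance,
#'   PSP gains and rheobase) and `sweeps[[temp]]$evoked/rest/steps`.
#' @export
simulate_cell_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p0 <- cfg$params
  temps <- as.character(cfg$temperatures)
  flat <- p0$condition %in% c("trpv3_block", "trpv3_ko")
  fates <- c("NEVER", "STOP", "STAY", "START")
  probs <- cfg$fate_fractions[c("never", "stop", "stay", "start")]
  cells <- vector("list", cfg$n_cells)
  pos_steps <- cfg$step_amplitudes[cfg$step_amplitudes > 0]
  for (ci in seq_len(cfg$n_cells)) {
    fate <- sample(fates, 1, prob = probs)
    d_off <- rnorm(1, 0, cfg$cell_sd_depol)
    r_off <- rnorm(1, 0, cfg$cell_sd_rmp)
    rin_f <- exp(rnorm(1, 0, cfg$cell_sd_log_rin))
    pars <- p0
    pars$depol_to_threshold_mV <- pmax(p0$depol_to_threshold_mV + d_off, 2)
    pars$rmp_mV <- p0$rmp_mV + r_off
    pars$rin_MOhm <- p0$rin_MOhm * rin_f
    pars$psp_gain_mV <- setNames(
      fate_psp_gain(fate, pars$depol_to_threshold_mV[temps], flat = flat),
      temps)
    st <- pars$base_level_mV + pars$depol_to_threshold_mV[temps]
    rheo_true <- vapply(temps, function(tl) {
      need <- (st[[tl]] - (-80)) / (pars$rin_MOhm[[tl]] * 1e-3)
      hit <- pos_steps[pos_steps * pars$rin_MOhm[[tl]] * 1e-3 - 80 > st[[tl]]]
      if (length(hit)) min(hit) else NA_real_
    }, numeric(1))
    sweeps <- list()
    for (tl in temps) {
      ev <- lapply(seq_len(cfg$n_sweeps_per_temp), function(k)
        simulate_sweep(pars, as.numeric(tl), cfg$stim_strength, cfg$noise_sd,
                       fs = cfg$fs, duration = cfg$sweep_duration,
                       stim_onset = cfg$stim_onset, sweep_index = k))
      n_rest <- round(cfg$sweep_duration * cfg$fs)
      rest <- sweep_trace(
        rep(pars$rmp_mV[[tl]], n_rest) +
          filtered_noise(n_rest, cfg$fs, cfg$noise_sd),
        fs = cfg$fs, stim_onset = cfg$sweep_duration,
        temperature = as.numeric(tl), sweep_index = 1L)
      steps <- if (cfg$include_steps)
        simulate_step_protocol(pars, as.numeric(tl), cfg$step_amplitudes,
                               fs = cfg$fs, noise_sd = cfg$noise_sd)
      else list()
      sweeps[[tl]] <- list(evoked = ev, rest = rest, steps = steps)
    }
    cells[[ci]] <- list(
      cell_id = sprintf("cell%03d", ci),
      age_group = cfg$age_group, condition = cfg$condition,
      intended_fate = fate,
      ground_truth = list(
        rmp_mV = pars$rmp_mV[temps],
        st_mV = st,
        depol_to_threshold_mV = pars$depol_to_threshold_mV[temps],
        rin_MOhm = pars$rin_MOhm[temps],
        psp_gain_mV = pars$psp_gain_mV[temps],
        ipsp_gain_mV = pars$ipsp_gain_mV[temps],
        rheobase_pA = rheo_true),
      params = pars,
      sweeps = sweeps)
  }
  structure(cells, class = "cell_population", config = cfg)
}

#' Simulate extracellular single units
#'
#' Trough-to-peak durations are drawn from a two-component Gaussian mixture
#' (narrow/wide, truncated positive); a mean waveform is synthesized from
#' piecewise cosine segments so its trough-to-peak separation equals the
#' drawn duration to within one sample; spike trains are piecewise-
#' homogeneous Poisson across baseline / fever / recovery periods with
#' class-specific rate multipliers.
#'
#' @param n_units number of units.
#' @param narrow_frac mixture weight of the narrow (putative interneuron)
#'   component, in `[0, 1]`.
#' @param modes,sds component means and SDs of the duration mixture, ms.
#' @param waveform_fs waveform sampling rate in Hz.
#' @param period_min length of each recording period in minutes (three
#'   periods: baseline, fever, recovery).
#' @param rate_multipliers list with `narrow` and `wide` length-3 multiplier
#'   vectors (baseline, fever, recovery); both fever multipliers exceed 1 by
#'   default, matching increased firing of both classes at fever temperature.
#' @param base_rate_meanlog,base_rate_sdlog log-normal parameters of the
#'   per-unit baseline firing rate (Hz).
#' @param seed integer seed.
#' @return list of unit records (class `"unit_population"`) with fields
#'   `unit_id`, `spike_times`, `mean_waveform`, `waveform_fs`, and a
#'   `ground_truth` list (`class`, `duration_ms`, `base_rate_hz`,
#'   `multipliers`); the period definitions are attached as attribute
#'   `"periods"` (see [period_defs()]).
#' @export
simulate_units <- function(n_units = 633L, narrow_frac = 0.22,
                           modes = c(0.35, 0.95), sds = c(0.05, 0.15),
                           waveform_fs = 30000, period_min = 45,
                           rate_multipliers = list(narrow = c(1, 1.4, 1),
                                                   wide = c(1, 1.4, 1)),
                           base_rate_meanlog = log(3), base_rate_sdlog = 0.5,
                           seed = 1L) {
  if (narrow_frac < 0 || narrow_frac > 1)
    stop("narrow_frac must lie in [0, 1]")
  set.seed(seed)
  periods <- period_defs(period_min = period_min)
  units <- vector("list", n_units)
  for (ui in seq_len(n_units)) {
    cls <- if (runif(1) < narrow_frac) "narrow" else "wide"
    ki <- if (cls == "narrow") 1L else 2L
    dur <- -1
    while (dur <= 0.05) dur <- rnorm(1, modes[ki], sds[ki])
    wf <- synth_waveform(dur, waveform_fs)
    base_rate <- exp(rnorm(1, base_rate_meanlog, base_rate_sdlog))
    mult <- rate_multipliers[[cls]]
    st <- unlist(lapply(seq_len(nrow(periods)), function(p) {
      r <- base_rate * mult[p]
      k <- rpois(1, r * (periods$end_s[p] - periods$start_s[p]))
      sort(runif(k, periods$start_s[p], periods$end_s[p]))
    }))
    units[[ui]] <- list(
      unit_id = sprintf("unit%04d", ui),
      spike_times = st, mean_waveform = wf, waveform_fs = waveform_fs,
      ground_truth = list(class = cls, duration_ms = dur,
                          base_rate_hz = base_rate, multipliers = mult))
  }
  structure(units, class = "unit_population", periods = periods)
}

# Mean-waveform synthesis: monotone cosine segments guarantee the global
# trough and the subsequent peak sit exactly on the intended samples.
synth_waveform <- function(duration_ms, fs) {
  dt <- round(duration_ms / 1000 * fs)
  n_pre <- round(0.5 / 1000 * fs)          # descent into the trough
  n_tail <- round(0.6 / 1000 * fs)         # decay after the peak
  i_trough <- n_pre + 1L
  i_peak <- i_trough + max(1L, dt)
  n <- i_peak + n_tail
  wf <- numeric(n)
  wf[1:i_trough] <- -(1 - cos(pi * (0:(i_trough - 1)) / (i_trough - 1))) / 2
  rise <- i_trough:i_peak
  wf[rise] <- -1 + 1.4 * (1 - cos(pi * (rise - i_trough) / (i_peak - i_trough))) / 2
  tail_idx <- (i_peak + 1L):n
  wf[tail_idx] <- 0.4 * cos(pi * (tail_idx - i_peak) / (2 * n_tail))
  wf
}

#' Simulate a body-temperature telemetry series
#'
#' Samples at a fixed cadence around a stable baseline, with optional planted
#' fever excursions (raised-cosine bumps), an optional linear heating ramp,
#' and event annotations at configured times.
#'
#' @param seed integer seed.
#' @param duration_h recording length in hours (default 6).
#' @param interval_min sampling cadence in minutes (default 5).
#' @param baseline baseline temperature in degrees C (default 36.5).
#' @param noise_sd SD of baseline noise in degrees C, truncated at
#'   `max_fluct` so the stated maximum fluctuation holds.
#' @param max_fluct bound on baseline fluctuation (degrees C).
#' @param excursions data frame with columns `onset_s`, `peak_C`,
#'   `duration_s`: raised-cosine excursions added to the baseline.
#' @param ramp optional list `list(t0 = , rate = , target = )`: from `t0`
#'   seconds the temperature rises at `rate` degrees C per second until
#'   `target`, then holds.
#' @param events data frame with columns `label`
#'   (ambulation/LPC/seizure_onset) and `time_s`, or NULL.
#' @param subject_id,genotype metadata labels.
#' @return a list of class `"tb_series"` with `time_s`, `temp_C`, `events`,
#'   `subject_id`, `genotype`.
#' @export
simulate_tb <- function(seed = 1L, duration_h = 6, interval_min = 5,
                        baseline = 36.5, noise_sd = 0, max_fluct = 0.5,
                        excursions = NULL, ramp = NULL, events = NULL,
                        subject_id = "sim", genotype = "wt") {
  if (interval_min <= 0) stop("interval_min must be positive")
  set.seed(seed)
  time_s <- seq(0, duration_h * 3600, by = interval_min * 60)
  temp <- rep(baseline, length(time_s))
  if (noise_sd > 0) {
    z <- rnorm(length(time_s), 0, noise_sd)
    temp <- temp + pmin(max_fluct, pmax(-max_fluct, z))
  }
  if (!is.null(excursions) && nrow(excursions) > 0) {
    for (e in seq_len(nrow(excursions))) {
      rel <- (time_s - excursions$onset_s[e]) / excursions$duration_s[e]
      inb <- rel >= 0 & rel <= 1
      temp[inb] <- temp[inb] +
        (excursions$peak_C[e] - baseline) * sin(pi * rel[inb])^2
    }
  }
  if (!is.null(ramp)) {
    after <- time_s >= ramp$t0
    base_at <- temp[which(after)[1]]
    ramped <- base_at + ramp$rate * (time_s[after] - ramp$t0)
    if (!is.null(ramp$target)) ramped <- pmin(ramped, ramp$target)
    temp[after] <- ramped
  }
  tb_series(time_s, temp, events = events, subject_id = subject_id,
            genotype = genotype)
}

#' Construct a body-temperature series object
#'
#' @param time_s strictly increasing sample times in seconds.
#' @param temp_C temperatures in degrees C (must lie in (20, 45)).
#' @param events data frame with `label` and `time_s` columns, or NULL.
#' @param subject_id,genotype metadata labels.
#' @return a list of class `"tb_series"`.
#' @export
tb_series <- function(time_s, temp_C, events = NULL, subject_id = NA,
                      genotype = NA) {
  if (length(time_s) != length(temp_C)) stop("time and temperature lengths differ")
  if (is.unsorted(time_s, strictly = TRUE)) stop("time_s must be strictly increasing")
  if (any(temp_C <= 20 | temp_C >= 45))
    stop("temperatures outside the plausible (20, 45) degree C range")
  if (!is.null(events)) {
    if (!all(c("label", "time_s") %in% names(events)))
      stop("events must have columns label and time_s")
    bad <- setdiff(unique(events$label), c("ambulation", "LPC", "seizure_onset"))
    if (length(bad)) stop("unknown event labels: ", paste(bad, collapse = ", "))
  }
  structure(list(time_s = as.numeric(time_s), temp_C = as.numeric(temp_C),
                 events = events, subject_id = subject_id, genotype = genotype),
            class = "tb_series")
}
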