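# Per-sweep and per-cell feature extraction from current-clamp traces:
# resting potential, spike detection, the second-derivative spike-threshold
# criterion, PSP peak and late component, input resistance, rheobase, F-I
# curves and evoked spike counts.

pre_stim_window <- function(sweep, pre_ms = 100) {
  t1 <- sweep$stim_onset
  t0 <- max(0, t1 - pre_ms / 1000)
  c(t0, t1)
}

window_idx <- function(sweep, window) {
  n <- length(sweep$vm)
  i0 <- max(1L, floor(window[1] * sweep$fs) + 1L)
  i1 <- min(n, ceiling(window[2] * sweep$fs))
  if (i1 < i0) integer(0) else i0:i1
}

baseline_of <- function(sweep, pre_ms = 100) {
  idx <- window_idx(sweep, pre_stim_window(sweep, pre_ms))
  mean(sweep$vm[idx])
}

# Zero-phase low-pass used before differentiating.
smooth_vm <- function(vm, fs, cutoff_hz = 2000) {
  wc <- cutoff_hz / (fs / 2)
  if (wc >= 1) return(vm)
  bf <- signal::butter(2, wc, type = "low")
  as.numeric(signal::filtfilt(bf, vm))
}

#' Resting membrane potential of a sweep
#'
#' Mean membrane potential over a pre-stimulus window during which no current
#' is injected.
#'
#' @param sweep a [sweep_trace()].
#' @param pre_window numeric interval `c(t0, t1)` in seconds; must end at or
#'   before the stimulus onset.  Default: the 100 ms immediately before the
#'   stimulus (or the whole pre-stimulus span if shorter).
#' @return mV (scalar).
#' @export
estimate_rmp <- function(sweep, pre_window = NULL) {
  if (is.null(pre_window)) pre_window <- pre_stim_window(sweep)
  if (pre_window[2] > sweep$stim_onset + 1e-12)
    stop("pre_window overlaps the stimulus")
  idx <- window_idx(sweep, pre_window)
  if (length(idx) == 0) stop("pre_window contains no samples")
  ic <- sweep$i_command
  if (length(ic) > 1 && any(ic[idx] != 0))
    stop("current injected during the pre_window")
  mean(sweep$vm[idx])
}

#' Detect spikes in a sweep
#'
#' A spike is an upward crossing of dV/dt > 20 mV/ms sustained for at least
#' 0.1 ms, or any sample above -20 mV.  Each event carries the detection
#' take-off (time and Vm at the criterion crossing), the spike peak, and the
#' afterhyperpolarization minimum (minimum Vm within 20 ms after the peak).
#' Events closer than the 2 ms absolute refractory window to the previous
#' detection are suppressed.
#'
#' @param sweep a [sweep_trace()].
#' @param window analysis interval `c(t0, t1)` in seconds (default: the
#'   whole sweep).
#' @param dvdt_crit detection slope criterion in mV/ms.
#' @param sustain_ms minimal duration the slope criterion must hold.
#' @param v_crit absolute voltage criterion in mV.
#' @param refractory_ms minimal event spacing.
#' @return data frame with one row per event: `t_threshold`, `v_threshold`,
#'   `t_peak`, `v_peak`, `v_ahp_min`, `i_onset`, `i_peak` (sample indices).
#' @export
detect_spikes <- function(sweep, window = NULL, dvdt_crit = 20,
                          sustain_ms = 0.1, v_crit = -20, refractory_ms = 2) {
  vm <- sweep$vm
  fs <- sweep$fs
  if (is.null(window)) window <- c(0, length(vm) / fs)
  idx <- window_idx(sweep, window)
  empty <- data.frame(t_threshold = numeric(0), v_threshold = numeric(0),
                      t_peak = numeric(0), v_peak = numeric(0),
                      v_ahp_min = numeric(0), i_onset = integer(0),
                      i_peak = integer(0))
  if (length(idx) < 3) return(empty)
  dvdt <- c(diff(vm) * fs / 1000, 0)            # mV/ms at each sample
  fast <- dvdt > dvdt_crit
  nsus <- max(1L, round(sustain_ms / 1000 * fs))
  sustained <- fast
  if (nsus > 1) {
    run <- stats::filter(as.numeric(fast), rep(1, nsus), sides = 1)
    sustained <- !is.na(run) & run == nsus
    # mark the start of each sustained run, not its end
    sustained <- c(sustained[-seq_len(nsus - 1)], rep(FALSE, nsus - 1)) &
      fast
  }
  # candidate runs are found on the whole trace, then events are kept when
  # their onset lies inside the window, so a window opening mid-spike does
  # not fabricate an event at its first sample
  cand_idx <- which(sustained | vm > v_crit)
  if (length(cand_idx) == 0) return(empty)
  onsets <- cand_idx[c(TRUE, diff(cand_idx) > 1)]
  onsets <- onsets[onsets >= idx[1] & onsets <= idx[length(idx)]]
  events <- list()
  nref <- max(1L, round(refractory_ms / 1000 * fs))
  last <- -Inf
  for (i0 in onsets) {
    if (i0 - last < nref) next
    # peak: maximum until Vm next falls back below the take-off value, or 5 ms
    lookahead <- min(length(vm), i0 + round(0.005 * fs))
    seg <- vm[i0:lookahead]
    i_pk <- i0 + which.max(seg) - 1L
    ahp_end <- min(length(vm), i_pk + round(0.020 * fs))
    v_ahp <- min(vm[i_pk:ahp_end])
    events[[length(events) + 1]] <- data.frame(
      t_threshold = (i0 - 1) / fs, v_threshold = vm[i0],
      t_peak = (i_pk - 1) / fs, v_peak = vm[i_pk],
      v_ahp_min = v_ahp, i_onset = i0, i_peak = i_pk)
    last <- i0
  }
  if (length(events) == 0) return(empty)
  do.call(rbind, events)
}

#' Spike threshold by the second-derivative criterion
#'
#' The spike threshold is the membrane potential at which the second
#' derivative of Vm first exceeds the mean plus 5 SDs of its pre-stimulus
#' distribution.  Vm is smoothed with a zero-phase 2 kHz low-pass before
#' double differencing (scaled by fs^2); searching back from the spike peak,
#' the exceedance run containing the upstroke is located and the Vm of its
#' earliest sample (taken from the raw trace) is returned.
#'
#' @param sweep a [sweep_trace()].
#' @param spike one row of the data frame returned by [detect_spikes()].
#' @param pre_window pre-stimulus reference interval (default: 100 ms before
#'   stimulus onset).
#' @param n_sd exceedance criterion in SDs of the pre-stimulus second
#'   derivative (default 5).
#' @param search_ms how far back from the peak the take-off may lie
#'   (default 10 ms); spike initiation belongs to the immediate upstroke,
#'   so distant chance exceedances are not mistaken for it.
#' @return threshold Vm in mV, or `NA` (with attribute
#'   `"estimate_failed" = TRUE`) when the criterion is never crossed within
#'   the search span before the peak.
#' @export
estimate_spike_threshold <- function(sweep, spike, pre_window = NULL,
                                     n_sd = 5, search_ms = 10) {
  if (is.null(pre_window)) pre_window <- pre_stim_window(sweep)
  if (pre_window[2] > sweep$stim_onset + 1e-12)
    stop("pre_window overlaps the stimulus")
  vm <- sweep$vm
  fs <- sweep$fs
  vs <- smooth_vm(vm, fs)
  d2 <- c(0, diff(vs, differences = 2) * fs^2, 0)   # aligned with samples
  pre_idx <- window_idx(sweep, pre_window)
  pre_idx <- pre_idx[pre_idx > 2 & pre_idx < length(vm) - 1]
  crit <- mean(d2[pre_idx]) + n_sd * sd(d2[pre_idx])
  i_pk <- spike$i_peak[1]
  i_lo <- max(1L, i_pk - round(search_ms / 1000 * fs))
  i <- i_pk
  while (i > i_lo && d2[i] <= crit) i <- i - 1L # find the exceedance run
  if (i <= i_lo || d2[i] <= crit)
    return(structure(NA_real_, estimate_failed = TRUE))
  while (i > 1 && d2[i - 1] > crit) i <- i - 1L # walk to its earliest sample
  vm[i]
}

#' Depolarization required to reach spike threshold
#'
#' @param st spike threshold in mV.
#' @param baseline pre-stimulus baseline of the same sweep in mV.
#' @return `st - baseline`, mV.
#' @export
depolarization_to_threshold <- function(st, baseline) {
  if (!is.finite(st) || !is.finite(baseline)) return(NA_real_)
  st - baseline
}

# Spans (sample index ranges) covered by detected spikes: take-off to 20 ms
# past the peak (the AHP window).
spike_spans <- function(sweep, events) {
  if (nrow(events) == 0) return(integer(0))
  unlist(lapply(seq_len(nrow(events)), function(k) {
    events$i_onset[k]:min(length(sweep$vm),
                          events$i_peak[k] + round(0.020 * sweep$fs))
  }))
}

#' Evoked PSP peak across sweeps at one temperature
#'
#' Maximum deflection of Vm above the pre-stimulus baseline within the
#' post-stimulus window, computed per sweep and summarized as the median
#' across sweeps.  Only spike-free sweeps are used; when every sweep spikes,
#' spikes are excised (take-off to end of the afterhyperpolarization) and
#' the remaining samples are used.
#'
#' @param sweeps list of [sweep_trace()] at one temperature.
#' @param window post-stimulus interval in seconds relative to stimulus
#'   onset (default `c(0.0025, 0.05)`).
#' @param summary `"median"` (default) or `"mean"` across sweeps.
#' @return mV (scalar).
#' @export
psp_peak <- function(sweeps, window = c(0.0025, 0.05), summary = "median") {
  vals <- psp_values(sweeps, window, statistic = "max")
  summarize_sweeps(vals, summary)
}

#' Late PSP component across sweeps at one temperature
#'
#' Mean signed deflection of Vm relative to the pre-stimulus baseline over a
#' late post-stimulus window where inhibition dominates (more negative means
#' stronger net inhibition), summarized as the median across spike-free
#' sweeps.
#'
#' @param sweeps list of [sweep_trace()] at one temperature.
#' @param late_window interval in seconds relative to stimulus onset
#'   (default `c(0.05, 0.1)`).
#' @param summary `"median"` (default) or `"mean"`.
#' @return mV (scalar, signed).
#' @export
late_psp <- function(sweeps, late_window = c(0.05, 0.1), summary = "median") {
  vals <- psp_values(sweeps, late_window, statistic = "mean")
  summarize_sweeps(vals, summary)
}

psp_values <- function(sweeps, window, statistic) {
  if (length(sweeps) == 0) stop("no sweeps supplied")
  per_sweep <- function(sw, excise) {
    base <- baseline_of(sw)
    abs_win <- sw$stim_onset + window
    idx <- window_idx(sw, abs_win)
    ev <- detect_spikes(sw, evoked_window(sw))
    if (nrow(ev) > 0) {
      if (!excise) return(NA_real_)
      idx <- setdiff(idx, spike_spans(sw, ev))
    }
    if (length(idx) == 0) return(NA_real_)
    x <- sw$vm[idx] - base
    if (statistic == "max") max(x) else mean(x)
  }
  vals <- vapply(sweeps, per_sweep, numeric(1), excise = FALSE)
  if (all(is.na(vals)))
    vals <- vapply(sweeps, per_sweep, numeric(1), excise = TRUE)
  if (all(is.na(vals))) stop("no usable post-stimulus samples")
  vals
}

summarize_sweeps <- function(vals, summary) {
  summary <- match.arg(summary, c("median", "mean"))
  if (summary == "median") median(vals, na.rm = TRUE) else mean(vals, na.rm = TRUE)
}

# Default evoked-spike analysis window: 150 ms starting 2.5 ms post-stimulus.
evoked_window <- function(sweep, start_ms = 2.5, length_ms = 150) {
  sweep$stim_onset + c(start_ms, start_ms + length_ms) / 1000
}

#' Input resistance from a subthreshold current step
#'
#' Steady-state voltage deflection divided by the step amplitude; the steady
#' state is the mean over the last 20 percent of the step.  Sweeps containing
#' spikes during the step are rejected.
#'
#' @param sweep a [sweep_trace()] whose `i_command` is a per-sample vector
#'   (or use `delta_i`, `step_window`).
#' @param delta_i step amplitude in pA (taken from `i_command` if omitted).
#' @param step_window step interval `c(t0, t1)` in seconds (inferred from
#'   `i_command` if omitted).
#' @return megaohms (scalar).
#' @export
input_resistance <- function(sweep, delta_i = NULL, step_window = NULL) {
  ic <- sweep$i_command
  if (is.null(step_window)) {
    if (length(ic) <= 1) stop("step_window required when i_command is scalar")
    on <- which(ic != 0)
    if (length(on) == 0) stop("no current step found in i_command")
    step_window <- c((on[1] - 1) / sweep$fs, on[length(on)] / sweep$fs)
  }
  if (is.null(delta_i)) {
    if (length(ic) <= 1) stop("delta_i required when i_command is scalar")
    delta_i <- ic[which(ic != 0)[1]]
  }
  if (delta_i == 0) stop("delta_i must be nonzero")
  ev <- detect_spikes(sweep, step_window)
  if (nrow(ev) > 0) stop("spike detected during the step; sweep rejected")
  idx <- window_idx(sweep, step_window)
  tail_idx <- idx[idx >= idx[1] + floor(0.8 * length(idx))]
  pre_idx <- window_idx(sweep, c(max(0, step_window[1] - 0.1), step_window[1]))
  dv <- mean(sweep$vm[tail_idx]) - mean(sweep$vm[pre_idx])
  (dv / delta_i) * 1000        # mV per pA -> megaohm
}

#' Rheobase from an ascending step protocol
#'
#' The smallest step amplitude whose sweep contains at least one detected
#' spike; flagged undefined (NA) when no sweep spikes.
#'
#' @param step_sweeps list of step [sweep_trace()] objects with per-sample
#'   `i_command`, amplitudes strictly ascending.
#' @return pA, or NA with attribute `"undefined" = TRUE`.
#' @export
rheobase <- function(step_sweeps) {
  amps <- vapply(step_sweeps, step_amplitude, numeric(1))
  if (is.unsorted(amps, strictly = TRUE)) stop("step amplitudes must ascend")
  counts <- vapply(step_sweeps, step_spike_count, numeric(1))
  hit <- which(counts >= 1)
  if (length(hit) == 0) return(structure(NA_real_, undefined = TRUE))
  amps[hit[1]]
}

step_amplitude <- function(sweep) {
  ic <- sweep$i_command
  if (length(ic) <= 1) return(as.numeric(ic))
  on <- which(ic != 0)
  if (length(on) == 0) 0 else ic[on[1]]
}

step_window_of <- function(sweep) {
  ic <- sweep$i_command
  on <- which(ic != 0)
  if (length(on) == 0) return(NULL)
  c((on[1] - 1) / sweep$fs, on[length(on)] / sweep$fs)
}

step_spike_count <- function(sweep) {
  w <- step_window_of(sweep)
  if (is.null(w)) w <- c(0, length(sweep$vm) / sweep$fs)
  nrow(detect_spikes(sweep, w))
}

#' F-I curve from a step protocol
#'
#' One (amplitude, spike count) pair per sweep, in protocol order; duplicate
#' amplitudes are kept as separate entries.
#'
#' @param step_sweeps list of step [sweep_trace()] objects.
#' @return data frame with columns `amplitude_pA` and `n_spikes`.
#' @export
fi_curve <- function(step_sweeps) {
  data.frame(amplitude_pA = vapply(step_sweeps, step_amplitude, numeric(1)),
             n_spikes = vapply(step_sweeps, step_spike_count, numeric(1)))
}

#' Mean evoked spike count per sweep
#'
#' Arithmetic mean of the per-sweep spike counts inside the evoked analysis
#' window (150 ms starting 2.5 ms post-stimulus by default).
#'
#' @param sweeps list of evoked [sweep_trace()] objects.
#' @param start_ms,length_ms analysis window geometry relative to stimulus.
#' @return count per sweep (scalar).
#' @export
mean_evoked_spikes <- function(sweeps, start_ms = 2.5, length_ms = 150) {
  counts <- vapply(sweeps, function(sw)
    nrow(detect_spikes(sw, evoked_window(sw, start_ms, length_ms))),
    numeric(1))
  mean(counts)
}

#' Net current-density difference between two I-V relations
#'
#' Element-wise difference of current densities recorded with a channel
#' opener alone versus opener plus blocker, on a matching voltage grid
#' (isolates the blocker-sensitive net current).
#'
#' @param density_opener,density_opener_plus_blocker data frames with
#'   columns `voltage_mV` and `density_pA_pF`, on identical voltage grids.
#' @return data frame `voltage_mV`, `density_pA_pF` of the difference.
#' @export
net_iv <- function(density_opener, density_opener_plus_blocker) {
  a <- density_opener
  b <- density_opener_plus_blocker
  if (nrow(a) != nrow(b) || any(a$voltage_mV != b$voltage_mV))
    stop("voltage grids do not match")
  data.frame(voltage_mV = a$voltage_mV,
             density_pA_pF = a$density_pA_pF - b$density_pA_pF)
}

#' Per-cell, per-temperature features
#'
#' Runs the full feature battery on one simulated or loaded cell record:
#' resting potential (from the unstimulated sweep), spike threshold and
#' depolarization-to-threshold (first spike of the first spiking evoked
#' sweep), spike height (peak above threshold) and afterhyperpolarization
#' depth (threshold minus AHP minimum), PSP peak, late PSP, evoked spike
#' counts, and (when a step protocol is present) input resistance from the
#' -50 pA step, rheobase and the F-I curve.  Missing features (e.g. the
#' threshold of a never-spiking cell) are explicit `NA`s.
#'
#' @param cell one element of a [simulate_cell_population()] result (or a
#'   structure of the same shape built from loaded data).
#' @param psp_window,late_window post-stimulus windows in seconds.
#' @return data frame with one row per temperature.
#' @export
cell_features <- function(cell, psp_window = c(0.0025, 0.05),
                          late_window = c(0.05, 0.1)) {
  rows <- lapply(names(cell$sweeps), function(tl) {
    sw <- cell$sweeps[[tl]]
    ev <- sw$evoked
    counts <- vapply(ev, function(s)
      nrow(detect_spikes(s, evoked_window(s))), numeric(1))
    st <- NA_real_
    depol <- NA_real_
    spike_height <- NA_real_
    ahp <- NA_real_
    first_spiking <- which(counts > 0)
    if (length(first_spiking) > 0) {
      s1 <- ev[[first_spiking[1]]]
      # the threshold is read from the sweep's first post-stimulus spike
      # (its take-off may precede the counting window's 2.5 ms start)
      events <- detect_spikes(s1, c(s1$stim_onset, length(s1$vm) / s1$fs))
      st <- as.numeric(estimate_spike_threshold(s1, events[1, ]))
      depol <- depolarization_to_threshold(st, baseline_of(s1))
      if (is.finite(st)) {
        spike_height <- events$v_peak[1] - st
        ahp <- st - events$v_ahp_min[1]
      }
    }
    rin <- NA_real_
    rheo <- NA_real_
    if (length(sw$steps) > 0) {
      amps <- vapply(sw$steps, step_amplitude, numeric(1))
      i_rin <- which(amps == -50)
      if (length(i_rin) == 1)
        rin <- tryCatch(input_resistance(sw$steps[[i_rin]]),
                        error = function(e) NA_real_)
      pos <- sw$steps[amps > 0]
      if (length(pos) > 0) rheo <- as.numeric(rheobase(pos))
    }
    data.frame(
      cell_id = cell$cell_id, temperature = as.numeric(tl),
      rmp = if (!is.null(sw$rest)) estimate_rmp(sw$rest) else NA_real_,
      st = st, depol_to_threshold = depol,
      psp_peak = psp_peak(ev, psp_window),
      late_psp = late_psp(ev, late_window),
      rin = rin, rheobase = rheo,
      mean_evoked_spikes = mean(counts),
      n_spiking_sweeps = sum(counts > 0),
      n_sweeps = length(ev),
      spike_height = spike_height, ahp = ahp)
  })
  do.call(rbind, rows)
}

#' Feature table for a whole population
#'
#' @param population a `"cell_population"` (see [simulate_cell_population()]).
#' @param ... passed to [cell_features()].
#' @return data frame, one row per cell and temperature.
#' @export
extract_features <- function(population, ...) {
  do.call(rbind, lapply(population, cell_features, ...))
}
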