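# Readers and writers for the package's plain-text formats: long-format CSV
# sweep containers, unit and telemetry tables, and YAML run manifests.

#' Write a cell population to a long-format CSV sweep container
#'
#' One row per sample with columns `cell_id`, `temperature`, `protocol`
#' (evoked/rest/step), `sweep`, `time_s`, `vm_mV`, `fs`, `stim_onset_s`,
#' `i_command_pA`.  The schema is self-describing: every sweep carries its
#' sampling rate, stimulus onset and (constant) command current.
#'
#' @param population a `"cell_population"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(population, path) {
  rows <- list()
  for (cell in population) {
    for (tl in names(cell$sweeps)) {
      sw <- cell$sweeps[[tl]]
      emit <- function(s, protocol, k) {
        ic <- if (length(s$i_command) > 1) step_amplitude(s) else s$i_command
        data.frame(cell_id = cell$cell_id, temperature = as.numeric(tl),
                   protocol = protocol, sweep = k,
                   time_s = (seq_along(s$vm) - 1) / s$fs, vm_mV = s$vm,
                   fs = s$fs, stim_onset_s = s$stim_onset, i_command_pA = ic)
      }
      for (k in seq_along(sw$evoked))
        rows[[length(rows) + 1]] <- emit(sw$evoked[[k]], "evoked", k)
      if (!is.null(sw$rest))
        rows[[length(rows) + 1]] <- emit(sw$rest, "rest", 1L)
      for (k in seq_along(sw$steps))
        rows[[length(rows) + 1]] <- emit(sw$steps[[k]], "step", k)
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format CSV sweep container
#'
#' Validates the schema written by [write_sweeps()]; a sweep with a missing
#' or non-finite `fs` or `stim_onset_s` raises an error naming the offending
#' cell and sweep.  Step sweeps are rebuilt with a per-sample command vector
#' covering the 0.1-0.6 s step interval.
#'
#' @param path CSV path.
#' @return a list of cell records shaped like [simulate_cell_population()]
#'   output (without ground-truth labels), class `"cell_population"`.
#' @export
read_sweeps <- function(path) {
  df <- read.csv(path)
  need <- c("cell_id", "temperature", "protocol", "sweep", "time_s", "vm_mV",
            "fs", "stim_onset_s", "i_command_pA")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sweep container missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    warning("empty sweep container")
    return(structure(list(), class = "cell_population"))
  }
  cells <- list()
  for (id in unique(df$cell_id)) {
    dc <- df[df$cell_id == id, ]
    sweeps <- list()
    for (tp in sort(unique(dc$temperature))) {
      dt <- dc[dc$temperature == tp, ]
      grab <- function(protocol) {
        dp <- dt[dt$protocol == protocol, ]
        lapply(sort(unique(dp$sweep)), function(k) {
          ds <- dp[dp$sweep == k, ]
          fs <- ds$fs[1]; so <- ds$stim_onset_s[1]
          if (!is.finite(fs))
            stop(sprintf("missing fs for %s / %g C / %s sweep %d",
                         id, tp, protocol, k))
          if (!is.finite(so))
            stop(sprintf("missing stim_onset for %s / %g C / %s sweep %d",
                         id, tp, protocol, k))
          ic <- ds$i_command_pA[1]
          if (protocol == "step") {
            icv <- numeric(nrow(ds))
            on <- ds$time_s >= so & ds$time_s < so + 0.5
            icv[on] <- ic
            ic <- icv
          }
          sweep_trace(ds$vm_mV, fs, so, i_command = ic, temperature = tp,
                      sweep_index = k)
        })
      }
      ev <- grab("evoked")
      rest <- grab("rest")
      steps <- grab("step")
      sweeps[[as.character(tp)]] <- list(
        evoked = ev, rest = if (length(rest)) rest[[1]] else NULL,
        steps = steps)
    }
    cells[[length(cells) + 1]] <- list(cell_id = id, sweeps = sweeps)
  }
  structure(cells, class = "cell_population")
}

#' Write a unit population to CSV files
#'
#' @param units a `"unit_population"`.
#' @param spikes_path long-format spike-time CSV (`unit_id`, `spike_time_s`).
#' @param waveforms_path waveform CSV (`unit_id`, `sample`, `amplitude`,
#'   `fs`).
#' @return invisibly, the two paths.
#' @export
write_units <- function(units, spikes_path, waveforms_path) {
  sp <- do.call(rbind, lapply(units, function(u)
    data.frame(unit_id = u$unit_id, spike_time_s = u$spike_times)))
  wf <- do.call(rbind, lapply(units, function(u)
    data.frame(unit_id = u$unit_id, sample = seq_along(u$mean_waveform),
               amplitude = u$mean_waveform, fs = u$waveform_fs)))
  write.csv(sp, spikes_path, row.names = FALSE)
  write.csv(wf, waveforms_path, row.names = FALSE)
  invisible(c(spikes_path, waveforms_path))
}

#' Read a unit population from CSV files
#'
#' @param spikes_path,waveforms_path paths written by [write_units()].
#' @return list of unit records, class `"unit_population"`.
#' @export
read_units <- function(spikes_path, waveforms_path) {
  sp <- read.csv(spikes_path)
  wf <- read.csv(waveforms_path)
  ids <- unique(wf$unit_id)
  units <- lapply(ids, function(id) {
    w <- wf[wf$unit_id == id, ]
    list(unit_id = id,
         spike_times = sort(sp$spike_time_s[sp$unit_id == id]),
         mean_waveform = w$amplitude[order(w$sample)],
         waveform_fs = w$fs[1])
  })
  structure(units, class = "unit_population")
}

#' Write / read a body-temperature series as CSV
#'
#' @param series a [tb_series()].
#' @param path samples CSV (`subject_id`, `time_s`, `temp_C`).
#' @param events_path optional events CSV (`label`, `time_s`).
#' @return `path`, invisibly.
#' @export
write_tb <- function(series, path, events_path = NULL) {
  write.csv(data.frame(subject_id = series$subject_id,
                       time_s = series$time_s, temp_C = series$temp_C),
            path, row.names = FALSE)
  if (!is.null(events_path) && !is.null(series$events))
    write.csv(series$events, events_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tb
#' @export
read_tb <- function(path, events_path = NULL) {
  df <- read.csv(path)
  ev <- if (!is.null(events_path)) read.csv(events_path) else NULL
  tb_series(df$time_s, df$temp_C, events = ev,
            subject_id = df$subject_id[1])
}
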