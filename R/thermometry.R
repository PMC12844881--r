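# Body-temperature telemetry analytics: summary statistics, fever-episode
# detection, heating rates, and behavioural latency metrics.

#' Summary statistics of a body-temperature series
#'
#' @param series a [tb_series()].
#' @return list with `median_C`, `max_fluctuation_C` (max minus median) and
#'   `min_fluctuation_C` (median minus min).
#' @export
summarize_tb <- function(series) {
  m <- median(series$temp_C)
  list(median_C = m,
       max_fluctuation_C = max(series$temp_C) - m,
       min_fluctuation_C = m - min(series$temp_C))
}

#' Detect fever-range episodes
#'
#' Maximal runs of consecutive samples strictly above the threshold; a
#' single sample above threshold counts as an episode of one cadence
#' duration.
#'
#' @param series a [tb_series()].
#' @param threshold_C fever threshold in degrees C (default 38.0).
#' @return data frame with one row per episode: `onset_s`, `offset_s`,
#'   `peak_C`, `duration_s` (run length times cadence).
#' @export
detect_fever_episodes <- function(series, threshold_C = 38.0) {
  hot <- series$temp_C > threshold_C
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_C = numeric(0), duration_s = numeric(0))
  if (!any(hot)) return(empty)
  cadence <- median(diff(series$time_s))
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  do.call(rbind, lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    data.frame(onset_s = series$time_s[i0], offset_s = series$time_s[i1],
               peak_C = max(series$temp_C[i0:i1]),
               duration_s = r$lengths[k] * cadence)
  }))
}

#' Heating rate between two time points
#'
#' Temperature difference over time difference, reading temperatures at the
#' samples nearest to `t0` and `t1`.
#'
#' @param series a [tb_series()].
#' @param t0,t1 times in seconds, `t0 < t1`, within the series.
#' @return degrees C per second.
#' @export
heating_rate <- function(series, t0, t1) {
  if (t0 >= t1) stop("need t0 < t1")
  rng <- range(series$time_s)
  if (t0 < rng[1] || t1 > rng[2]) stop("t0/t1 outside the recorded span")
  v0 <- series$temp_C[which.min(abs(series$time_s - t0))]
  v1 <- series$temp_C[which.min(abs(series$time_s - t1))]
  (v1 - v0) / (t1 - t0)
}

#' Behavioural latency metrics from annotated telemetry
#'
#' Temperatures are read at the sample nearest each event (no interpolation:
#' the 5-minute cadence would make it spuriously precise); latencies are
#' event-time differences.  Missing events yield `NA` fields flagged in
#' `missing`, so group summaries can exclude them.
#'
#' @param series a [tb_series()] with an `events` data frame.
#' @return list with `Tb_at_ambulation`, `Tb_at_LPC`, `Tb_at_seizure`,
#'   `time_to_LPC_s` (from the series start), `LPC_to_seizure_s`, and
#'   `missing` (character vector of absent events).
#' @export
latency_metrics <- function(series) {
  ev <- series$events
  if (is.null(ev)) ev <- data.frame(label = character(0), time_s = numeric(0))
  get_time <- function(lab) {
    i <- which(ev$label == lab)
    if (length(i) == 0) NA_real_ else ev$time_s[i[1]]
  }
  tb_at <- function(t) {
    if (is.na(t)) return(NA_real_)
    series$temp_C[which.min(abs(series$time_s - t))]
  }
  t_amb <- get_time("ambulation")
  t_lpc <- get_time("LPC")
  t_sz <- get_time("seizure_onset")
  if (!is.na(t_lpc) && !is.na(t_sz) && t_sz < t_lpc)
    stop("seizure onset precedes loss of postural control")
  missing <- c("ambulation", "LPC", "seizure_onset")[is.na(c(t_amb, t_lpc, t_sz))]
  list(Tb_at_ambulation = tb_at(t_amb),
       Tb_at_LPC = tb_at(t_lpc),
       Tb_at_seizure = tb_at(t_sz),
       time_to_LPC_s = if (is.na(t_lpc)) NA_real_ else t_lpc - series$time_s[1],
       LPC_to_seizure_s = if (is.na(t_lpc) || is.na(t_sz)) NA_real_
                          else t_sz - t_lpc,
       missing = missing)
}

#' Percent change of a group mean relative to a reference
#'
#' @param group_mean,reference_mean numeric scalars; `reference_mean != 0`.
#' @return percent.
#' @export
percent_change <- function(group_mean, reference_mean) {
  if (!is.finite(group_mean) || !is.finite(reference_mean))
    stop("means must be finite")
  if (reference_mean == 0) stop("reference mean is zero")
  100 * (group_mean - reference_mean) / reference_mean
}
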