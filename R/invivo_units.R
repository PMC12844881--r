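# Extracellular unit classification and period-restricted firing rates:
# band-pass filtering of mean waveforms, trough-to-peak duration,
# two-class k-means split of the duration distribution, inclusion filtering,
# and per-period (baseline / fever / recovery) rate normalization.

#' Period definitions for the thermal protocol
#'
#' Three consecutive periods (baseline, fever, recovery) of equal length;
#' only the last `analysis_min` minutes of each are used for mean firing
#' rates, to discount transients at period boundaries.
#'
#' @param period_min period length in minutes (default 45).
#' @param analysis_min analysed tail of each period in minutes (default 25).
#' @param start_s start of the baseline period in seconds.
#' @return data frame with `name`, `start_s`, `analysis_start_s`, `end_s`.
#' @export
period_defs <- function(period_min = 45, analysis_min = 25, start_s = 0) {
  if (analysis_min <= 0 || analysis_min > period_min)
    stop("analysis_min must lie in (0, period_min]")
  len <- period_min * 60
  st <- start_s + (0:2) * len
  data.frame(name = c("baseline", "fever", "recovery"),
             start_s = st, analysis_start_s = st + len - analysis_min * 60,
             end_s = st + len)
}

#' Zero-phase band-pass filter for mean waveforms
#'
#' @param waveform numeric vector of amplitude samples.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz (defaults 300 and 6000).
#' @return filtered waveform, same length.
#' @export
bandpass_waveform <- function(waveform, fs, lo = 300, hi = 6000) {
  ny <- fs / 2
  bf <- signal::butter(2, c(lo / ny, min(0.99, hi / ny)), type = "pass")
  # odd-reflection padding suppresses filtfilt edge transients on the short
  # snippets typical of mean waveforms
  n <- length(waveform)
  np <- min(n - 1, ceiling(3 * fs / lo))
  head_pad <- 2 * waveform[1] - waveform[(np + 1):2]
  tail_pad <- 2 * waveform[n] - waveform[(n - 1):(n - np)]
  padded <- c(head_pad, waveform, tail_pad)
  out <- as.numeric(signal::filtfilt(bf, padded))
  out[(np + 1):(np + n)]
}

#' Trough-to-peak duration of a mean waveform
#'
#' Time from the global minimum (trough) to the maximum of the samples that
#' follow it, in milliseconds.
#'
#' @param waveform numeric vector.
#' @param fs sampling rate in Hz.
#' @return ms, or `NA` (attribute `"unassignable" = TRUE`) when the trough
#'   is the final sample.
#' @export
trough_to_peak_ms <- function(waveform, fs) {
  i_tr <- which.min(waveform)
  if (i_tr >= length(waveform))
    return(structure(NA_real_, unassignable = TRUE))
  i_pk <- i_tr + which.max(waveform[(i_tr + 1):length(waveform)])
  (i_pk - i_tr) / fs * 1000
}

#' Two-class split of spike durations (narrow vs wide)
#'
#' Exact one-dimensional 2-means clustering of trough-to-peak durations:
#' the optimal two-class partition of the 2-means objective in one
#' dimension is always a contiguous split of the sorted values, so the
#' global optimum is found by scanning every split point for the minimal
#' within-class sum of squares (no random initialization, fully
#' deterministic).  The class with the smaller mean is narrow (putative
#' interneuron), the other wide (putative principal cell).  When several
#' splits tie, the boundary value goes to the wide class.
#'
#' @param durations numeric vector of durations in ms (n >= 2, finite).
#' @return list with `labels` (factor narrow/wide), `boundary_ms` (midpoint
#'   between the closest opposite-class pair), `centers` (sorted cluster
#'   means).
#' @export
split_two_classes <- function(durations) {
  if (length(durations) < 2 || !all(is.finite(durations)))
    stop("need at least two finite durations")
  if (diff(range(durations)) == 0)
    stop("all durations identical; classes unassignable")
  o <- order(durations)
  xs <- durations[o]
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- 1:(n - 1)
  # within-class SS of both sides for every contiguous split, via prefix sums
  w_left <- cs2[k] - cs[k]^2 / k
  w_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  wcss <- w_left + w_right
  # ties toward wide: the smallest narrow class among optimal splits
  k_best <- which(wcss <= min(wcss) + 1e-12 * (1 + min(wcss)))[1]
  lab <- rep("wide", n)
  lab[o[1:k_best]] <- "narrow"
  nrw <- xs[1:k_best]
  wde <- xs[(k_best + 1):n]
  list(labels = factor(lab, levels = c("narrow", "wide")),
       boundary_ms = (max(nrw) + min(wde)) / 2,
       centers = c(mean(nrw), mean(wde)))
}

#' Unit inclusion filter
#'
#' A unit is included when it has at least `min_spikes` spikes and its
#' spikes are present throughout the recording, operationalized as at least
#' one spike in each of `coverage_bins` equal divisions of the recording
#' span.  (Waveform-shape and refractory-period curation happen upstream.)
#'
#' @param unit a unit record with `spike_times`.
#' @param recording_span `c(t0, t1)` seconds.
#' @param min_spikes minimal spike count (default 900).
#' @param coverage_bins number of coverage bins (default 10).
#' @return logical.
#' @export
inclusion_filter <- function(unit, recording_span, min_spikes = 900,
                             coverage_bins = 10) {
  st <- unit$spike_times
  if (length(st) < min_spikes) return(FALSE)
  edges <- seq(recording_span[1], recording_span[2],
               length.out = coverage_bins + 1)
  counts <- table(cut(st, edges, include.lowest = TRUE))
  all(counts >= 1)
}

#' Mean firing rate per period
#'
#' Spike count within `[analysis_start_s, end_s)` of each period divided by
#' the analysed duration.
#'
#' @param unit a unit record with `spike_times` (seconds, sorted).
#' @param periods a [period_defs()] data frame.
#' @return named numeric vector, Hz per period.
#' @export
period_rates <- function(unit, periods) {
  st <- unit$spike_times
  r <- vapply(seq_len(nrow(periods)), function(p) {
    a <- periods$analysis_start_s[p]
    b <- periods$end_s[p]
    sum(st >= a & st < b) / (b - a)
  }, numeric(1))
  setNames(r, periods$name)
}

#' Normalize per-period rates to the baseline period
#'
#' @param rates named vector from [period_rates()]; must contain
#'   `"baseline"`.
#' @return rates divided by the baseline rate (baseline maps to 1), or all
#'   `NA` with attribute `"excluded" = TRUE` when the baseline rate is zero.
#' @export
normalize_rates <- function(rates) {
  b <- rates[["baseline"]]
  if (is.na(b) || b <= 0)
    return(structure(setNames(rep(NA_real_, length(rates)), names(rates)),
                     excluded = TRUE))
  rates / b
}

#' Classify and summarize a unit population
#'
#' Full in-vivo battery: band-pass each mean waveform, measure trough-to-peak
#' durations, apply the inclusion filter, split included units into narrow /
#' wide classes, and compute raw and baseline-normalized period rates.
#'
#' @param units a `"unit_population"` (see [simulate_units()]) or any list of
#'   unit records.
#' @param periods a [period_defs()] data frame (default: attribute of
#'   `units`, else the standard 45-minute protocol).
#' @param min_spikes,coverage_bins passed to [inclusion_filter()].
#' @return data frame with one row per unit: `unit_id`, `duration_ms`,
#'   `included`, `unit_class`, rate and normalized-rate columns per period.
#' @export
classify_units <- function(units, periods = NULL, min_spikes = 900,
                           coverage_bins = 10) {
  if (is.null(periods)) periods <- attr(units, "periods")
  if (is.null(periods)) periods <- period_defs()
  span <- c(min(periods$start_s), max(periods$end_s))
  rows <- lapply(units, function(u) {
    wf <- bandpass_waveform(u$mean_waveform, u$waveform_fs)
    dur <- trough_to_peak_ms(wf, u$waveform_fs)
    inc <- inclusion_filter(u, span, min_spikes, coverage_bins)
    r <- period_rates(u, periods)
    nr <- normalize_rates(r)
    data.frame(unit_id = u$unit_id, duration_ms = as.numeric(dur),
               included = inc,
               rate_baseline = r[["baseline"]], rate_fever = r[["fever"]],
               rate_recovery = r[["recovery"]],
               norm_baseline = nr[["baseline"]], norm_fever = nr[["fever"]],
               norm_recovery = nr[["recovery"]])
  })
  out <- do.call(rbind, rows)
  out$unit_class <- "unassigned"
  ok <- out$included & is.finite(out$duration_ms)
  if (sum(ok) >= 2 && diff(range(out$duration_ms[ok])) > 0) {
    sp <- split_two_classes(out$duration_ms[ok])
    out$unit_class[ok] <- as.character(sp$labels)
    attr(out, "boundary_ms") <- sp$boundary_ms
  }
  out
}
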