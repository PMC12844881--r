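# Thermal-fate classification: binary spiking status per cell per
# temperature, NEVER/STOP/STAY/START labels under the three-temperature and
# pairwise (36 -> 39) schemes, fate proportions, and the exact two-tailed
# binomial comparison used for proportion contrasts.

#' Binary spiking status at one temperature
#'
#' A cell counts as spiking at a temperature when at least `min_sweeps`
#' evoked sweeps contain at least one detected spike (default: one sweep,
#' the weakest natural criterion).
#'
#' @param features one row of the [cell_features()] table (or any list with
#'   `n_spiking_sweeps`).
#' @param min_sweeps minimal number of sweeps with a spike.
#' @return logical.
#' @export
spiking_flag <- function(features, min_sweeps = 1L) {
  n <- features$n_spiking_sweeps
  if (is.null(n) || is.na(n)) stop("n_spiking_sweeps missing")
  n >= min_sweeps
}

#' Thermal fate from per-temperature spiking flags
#'
#' Under the `three_temp` scheme the flags at 30, 36 and 39 degrees are used:
#' spiking at all three is STAY, at none NEVER; cells that spiked at 30 and
#' fell silent later are STOP; cells silent at 30 that started later are
#' START.  Non-monotone patterns (spiking lost and regained, or vice versa)
#' are labelled by their last transition and flagged `intermittent`.  Under
#' the `pairwise` scheme only the 36 and 39 degree flags are used:
#' (T,T) STAY, (T,F) STOP, (F,T) START, (F,F) NEVER.
#'
#' @param flags named logical vector of spiking flags; names are temperature
#'   labels (`"30"`, `"36"`, `"39"`).
#' @param scheme `"three_temp"` or `"pairwise"`.
#' @return list with `label` (one of NEVER/STOP/STAY/START) and
#'   `intermittent` (logical).
#' @export
classify_fate <- function(flags, scheme = c("three_temp", "pairwise")) {
  scheme <- match.arg(scheme)
  need <- if (scheme == "three_temp") c("30", "36", "39") else c("36", "39")
  if (!all(need %in% names(flags)) || anyNA(flags[need]))
    stop("missing spiking flag for temperature ",
         paste(setdiff(need, names(flags)[!is.na(flags)]), collapse = ", "))
  f <- as.logical(flags[need])
  if (scheme == "pairwise") {
    label <- if (f[1] && f[2]) "STAY" else if (f[1]) "STOP"
             else if (f[2]) "START" else "NEVER"
    return(list(label = label, intermittent = FALSE))
  }
  if (all(f)) return(list(label = "STAY", intermittent = FALSE))
  if (!any(f)) return(list(label = "NEVER", intermittent = FALSE))
  if (f[1] && !f[2] && !f[3]) return(list(label = "STOP", intermittent = FALSE))
  if (f[1] && f[2] && !f[3]) return(list(label = "STOP", intermittent = FALSE))
  if (!f[1] && f[2] && f[3]) return(list(label = "START", intermittent = FALSE))
  if (!f[1] && !f[2] && f[3]) return(list(label = "START", intermittent = FALSE))
  # non-monotone: label by the last transition, flag intermittent
  if (f[1] && !f[2] && f[3]) return(list(label = "START", intermittent = TRUE))
  list(label = "STOP", intermittent = TRUE)    # (F, T, F)
}

#' Fates for a whole feature table
#'
#' @param features a [extract_features()] table.
#' @param scheme `"three_temp"` or `"pairwise"`.
#' @param min_sweeps passed to [spiking_flag()].
#' @return data frame `cell_id`, `scheme`, `label`, `intermittent`.
#' @export
classify_fates <- function(features, scheme = c("three_temp", "pairwise"),
                           min_sweeps = 1L) {
  scheme <- match.arg(scheme)
  ids <- unique(features$cell_id)
  rows <- lapply(ids, function(id) {
    fx <- features[features$cell_id == id, ]
    flags <- setNames(vapply(seq_len(nrow(fx)), function(i)
      spiking_flag(fx[i, ], min_sweeps), logical(1)),
      as.character(fx$temperature))
    cf <- classify_fate(flags, scheme)
    data.frame(cell_id = id, scheme = scheme, label = cf$label,
               intermittent = cf$intermittent)
  })
  do.call(rbind, rows)
}

#' Fate proportions of a cohort
#'
#' @param fates a [classify_fates()] table (or any data frame with a
#'   `label` column).
#' @param condition optional condition label stored in the result.
#' @return data frame with one row per fate: `label`, `count`, `percent`,
#'   plus attributes `n_cells`, `scheme`, `condition`.
#' @export
fate_proportions <- function(fates, condition = NA_character_) {
  if (nrow(fates) == 0) stop("empty cohort")
  lv <- c("NEVER", "STOP", "STAY", "START")
  counts <- table(factor(fates$label, levels = lv))
  out <- data.frame(label = lv, count = as.integer(counts),
                    percent = 100 * as.integer(counts) / nrow(fates))
  structure(out, n_cells = nrow(fates),
            scheme = if ("scheme" %in% names(fates)) fates$scheme[1] else NA,
            condition = condition)
}

#' Exact two-tailed binomial test
#'
#' The two-tailed p-value is the total probability of all outcomes whose
#' point probability does not exceed that of the observed count:
#' `sum over i of P(X = i)` for all `i` with `P(X = i) <= P(X = k)`,
#' with `X ~ Binomial(n, p0)`.
#'
#' @param k observed successes.
#' @param n number of trials.
#' @param p0 reference proportion (must be supplied explicitly; typically the
#'   comparison condition's observed proportion).
#' @return two-tailed p-value.
#' @export
binomial_compare <- function(k, n, p0) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1")
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  pmf <- dbinom(0:n, n, p0)
  # tolerance guards against ties broken by floating-point rounding
  min(1, sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-12)]))
}

#' Percentage of spiking cells per temperature
#'
#' @param features a [extract_features()] table.
#' @param min_sweeps passed to [spiking_flag()].
#' @return data frame `temperature`, `n`, `n_spiking`, `percent`.
#' @export
percent_spiking_by_temperature <- function(features, min_sweeps = 1L) {
  if (nrow(features) == 0) stop("empty feature table")
  temps <- sort(unique(features$temperature))
  rows <- lapply(temps, function(tp) {
    fx <- features[features$temperature == tp, ]
    sp <- vapply(seq_len(nrow(fx)), function(i)
      spiking_flag(fx[i, ], min_sweeps), logical(1))
    data.frame(temperature = tp, n = nrow(fx), n_spiking = sum(sp),
               percent = 100 * mean(sp))
  })
  do.call(rbind, rows)
}
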