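#' Max-interval burst detection parameters
#'
#' The five-parameter max-interval scheme used throughout the package:
#' a burst opens at an interspike interval (ISI) no longer than
#' `max_begin_isi`, extends while ISIs stay within `max_end_isi`, adjacent
#' candidates closer than `min_ibi` are merged, and candidates shorter than
#' `min_duration` or smaller than `min_spikes` are discarded. Defaults are
#' the standard MEA set: 0.1 s / 0.2 s / 0.5 s / 0.05 s / 6 spikes.
#'
#' @param max_begin_isi Maximum ISI opening a burst, seconds.
#' @param max_end_isi Maximum ISI extending a burst, seconds
#'   (`>= max_begin_isi`).
#' @param min_ibi Minimum interburst interval, seconds; candidate bursts
#'   separated by less are merged.
#' @param min_duration Minimum burst duration (first to last spike), seconds.
#' @param min_spikes Minimum number of spikes per burst (`>= 2`).
#' @return A list of class `burst_params`.
#' @export
burst_params <- function(max_begin_isi = 0.1, max_end_isi = 0.2,
                         min_ibi = 0.5, min_duration = 0.05, min_spikes = 6) {
  stopifnot(max_begin_isi > 0, max_end_isi > 0, min_ibi > 0,
            min_duration > 0, min_spikes >= 2,
            max_end_isi >= max_begin_isi)
  structure(list(max_begin_isi = max_begin_isi, max_end_isi = max_end_isi,
                 min_ibi = min_ibi, min_duration = min_duration,
                 min_spikes = as.integer(min_spikes)),
            class = "burst_params")
}

#' Detect bursts in a spike train (max-interval method)
#'
#' Four steps, in order: (1) scan ISIs and open a candidate burst at spike
#' `i` whenever `ISI(i, i+1) <= max_begin_isi`; (2) extend the candidate
#' while subsequent ISIs are `<= max_end_isi`, close otherwise; (3) merge
#' consecutive candidates whose gap (next start minus previous end) is
#' strictly less than `min_ibi` — merging runs before size/duration
#' filtering, so two small candidates can combine into one valid burst;
#' (4) discard candidates with fewer than `min_spikes` spikes or shorter
#' than `min_duration`. Boundary conventions: ISI comparisons inclusive,
#' merge strict, retention inclusive.
#'
#' @param train A [spike_train()] (or bare numeric vector of sorted times).
#' @param params A [burst_params()].
#' @return A data.frame with one row per burst: `first_spike_index`,
#'   `last_spike_index` (1-based into the train), `t_start`, `t_end`
#'   (times of first/last spike, seconds), `n_spikes`, `duration`.
#'   Zero rows when no burst qualifies; trains with fewer than two spikes
#'   yield zero rows.
#' @examples
#' st <- spike_train(0, seq(0, 0.25, by = 0.05), t_end = 60)
#' detect_bursts(st)
#' @export
detect_bursts <- function(train, params = burst_params()) {
  stopifnot(inherits(params, "burst_params"))
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  empty <- data.frame(first_spike_index = integer(), last_spike_index = integer(),
                      t_start = numeric(), t_end = numeric(),
                      n_spikes = integer(), duration = numeric())
  n <- length(t)
  if (n < 2) return(empty)

  isi <- diff(t)
  # step 1-2: candidate spans
  starts <- integer(); ends <- integer()
  i <- 1L
  while (i < n) {
    if (isi[i] <= params$max_begin_isi) {
      j <- i + 1L
      while (j < n && isi[j] <= params$max_end_isi) j <- j + 1L
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(starts)) return(empty)

  # step 3: merge candidates separated by less than min_ibi
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(); out_e <- integer()
  if (length(starts) > 1) for (k in 2:length(starts)) {
    if (t[starts[k]] - t[me] < params$min_ibi) {
      me <- ends[k]
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[k]; me <- ends[k]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)

  # step 4: size and duration thresholds
  nsp <- out_e - out_s + 1L
  dur <- t[out_e] - t[out_s]
  keep <- nsp >= params$min_spikes & dur >= params$min_duration
  data.frame(first_spike_index = out_s[keep], last_spike_index = out_e[keep],
             t_start = t[out_s[keep]], t_end = t[out_e[keep]],
             n_spikes = nsp[keep], duration = dur[keep])
}

#' Interburst intervals
#'
#' Gaps between consecutive bursts of one train: each interval is the next
#' burst's start time minus the previous burst's end time.
#'
#' @param bursts A burst table from [detect_bursts()] (time-ordered,
#'   non-overlapping).
#' @return Numeric vector of length `max(0, nrow(bursts) - 1)`, seconds.
#' @export
interburst_intervals <- function(bursts) {
  if (nrow(bursts) < 2) return(numeric())
  bursts$t_start[-1] - bursts$t_end[-nrow(bursts)]
}

#' Burst table for a whole recording
#'
#' Runs [detect_bursts()] on every electrode and stacks the results into the
#' exportable long format.
#'
#' @param rec A [recording()].
#' @param params A [burst_params()].
#' @return data.frame with columns `electrode`, `burst_index`, `t_start`,
#'   `t_end`, `n_spikes`, `duration`.
#' @export
recording_bursts <- function(rec, params = burst_params()) {
  stopifnot(inherits(rec, "mea_recording"))
  per <- lapply(rec$trains, function(tr) {
    b <- detect_bursts(tr, params)
    if (nrow(b))
      data.frame(electrode = tr$electrode_id, burst_index = seq_len(nrow(b)),
                 b[c("t_start", "t_end", "n_spikes", "duration")])
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (!length(per))
    return(data.frame(electrode = integer(), burst_index = integer(),
                      t_start = numeric(), t_end = numeric(),
                      n_spikes = integer(), duration = numeric()))
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}
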