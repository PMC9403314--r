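FEATURE_NAMES <- c("n_spikes", "firing_rate", "mean_isi",
                   "pct_spikes_in_bursts",
                   "n_bursts", "bursts_per_min", "mean_burst_duration",
                   "mean_ibi")
SPIKE_FEATURES <- FEATURE_NAMES[1:4]
BURST_FEATURES <- FEATURE_NAMES[5:8]

#' Per-electrode spike and burst features
#'
#' The feature panel summarised per well and tracked against baseline:
#' firing rate, mean interspike interval, bursts per minute, mean burst
#' duration, percentage of spikes inside bursts, and mean interburst
#' interval, plus the raw spike and burst counts. Features that need at
#' least two events (mean ISI, mean IBI) are `NA` when undefined; `NA` is
#' the undefined marker throughout and never silently becomes zero.
#'
#' @param train A [spike_train()].
#' @param bursts Burst table from [detect_bursts()] on the same train.
#' @param duration Recording length in seconds (positive).
#' @return One-row data.frame with columns `n_spikes`, `firing_rate` (Hz),
#'   `mean_isi` (s), `pct_spikes_in_bursts` (0-100), `n_bursts`,
#'   `bursts_per_min`, `mean_burst_duration` (s), `mean_ibi` (s).
#' @export
electrode_features <- function(train, bursts = detect_bursts(train),
                               duration = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (is.null(duration)) duration <- train$t_end - train$t_start
  if (duration <= 0) stop("duration must be positive")
  n <- length(train$times)
  nb <- nrow(bursts)
  in_burst <- if (nb) sum(bursts$n_spikes) else 0L
  ibi <- interburst_intervals(bursts)
  data.frame(
    n_spikes = n,
    firing_rate = n / duration,
    mean_isi = if (n >= 2) mean(diff(train$times)) else NA_real_,
    pct_spikes_in_bursts = if (n > 0) 100 * in_burst / n else NA_real_,
    n_bursts = nb,
    bursts_per_min = nb / (duration / 60),
    mean_burst_duration = if (nb >= 1) mean(bursts$duration) else NA_real_,
    mean_ibi = if (length(ibi)) mean(ibi) else NA_real_
  )
}

#' Feature table for all electrodes of a recording
#'
#' @param rec A [recording()] (typically already passed through
#'   [filter_active_electrodes()]).
#' @param params A [burst_params()].
#' @return data.frame with one row per electrode: `electrode` plus the
#'   columns of [electrode_features()].
#' @export
recording_features <- function(rec, params = burst_params()) {
  stopifnot(inherits(rec, "mea_recording"))
  rows <- lapply(rec$trains, function(tr)
    cbind(electrode = tr$electrode_id,
          electrode_features(tr, detect_bursts(tr, params), rec$duration)))
  if (!length(rows)) {
    out <- data.frame(electrode = integer())
    for (f in FEATURE_NAMES) out[[f]] <- numeric()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Weighted mean and standard deviation
#'
#' The population-form weighted summary used for well-level statistics:
#' `mean = sum(w x) / sum(w)` and `sd = sqrt(sum(w (x - mean)^2) / sum(w))`.
#' Pairs where the value is `NA` are dropped together with their weights.
#'
#' @param values Numeric vector.
#' @param weights Non-negative weights, same length.
#' @return Named list `list(mean =, sd =, n =)` where `n` counts the pairs
#'   that contributed. All-`NA` values or all-zero weights yield `NA`
#'   results with a warning.
#' @export
weighted_summary <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights), all(weights >= 0, na.rm = TRUE))
  ok <- !is.na(values) & !is.na(weights)
  values <- values[ok]; weights <- weights[ok]
  if (!length(values) || sum(weights) == 0) {
    warning("no defined values with positive weight; summary is NA")
    return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  }
  m <- sum(weights * values) / sum(weights)
  s <- sqrt(sum(weights * (values - m)^2) / sum(weights))
  list(mean = m, sd = s, n = length(values))
}

#' Well-level weighted summary of the feature panel
#'
#' Summarises a recording's per-electrode features into weighted means and
#' SDs over active electrodes. With `weighting = "count"` (default), spike
#' features are weighted by each electrode's spike count and burst features
#' by its burst count, so electrodes with no bursts do not dilute burst
#' statistics; `"uniform"` weights every electrode equally.
#'
#' @param rec A [recording()], already active-filtered by the caller (use
#'   [filter_active_electrodes()]).
#' @param params A [burst_params()].
#' @param weighting `"count"` or `"uniform"`.
#' @return data.frame with one row per feature: `feature`, `weighted_mean`,
#'   `weighted_sd`, `n_active_electrodes`.
#' @export
well_summary <- function(rec, params = burst_params(),
                         weighting = c("count", "uniform")) {
  weighting <- match.arg(weighting)
  feat <- recording_features(rec, params)
  summarise_features(feat, weighting)
}

summarise_features <- function(feat, weighting = "count") {
  n_active <- nrow(feat)
  rows <- lapply(FEATURE_NAMES, function(f) {
    w <- if (weighting == "uniform" || n_active == 0) rep(1, n_active)
         else if (f %in% SPIKE_FEATURES) feat$n_spikes
         else feat$n_bursts
    s <- if (n_active == 0 || all(is.na(feat[[f]])) || sum(w, na.rm = TRUE) == 0)
      list(mean = NA_real_, sd = NA_real_, n = 0L)
    else weighted_summary(feat[[f]], w)
    data.frame(feature = f, weighted_mean = s$mean, weighted_sd = s$sd,
               n_active_electrodes = n_active)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fold change of a well summary relative to baseline
#'
#' Per-feature ratio of a timepoint's weighted mean to the same well's
#' baseline weighted mean, the normalisation used because baseline activity
#' varies from well to well. A summary compared against itself gives 1 for
#' every defined feature; a zero or undefined baseline mean yields `NA`
#' with a warning, never infinity.
#'
#' @param summary_t,summary_baseline Summaries from [well_summary()] for the
#'   same well.
#' @return data.frame `feature`, `fold_change`.
#' @export
fold_change <- function(summary_t, summary_baseline) {
  stopifnot(identical(summary_t$feature, summary_baseline$feature))
  base <- summary_baseline$weighted_mean
  bad <- is.na(base) | base == 0
  fc <- summary_t$weighted_mean / base
  fc[bad] <- NA_real_
  if (any(bad & !is.na(summary_t$weighted_mean)))
    warning("zero or undefined baseline mean for: ",
            paste(summary_t$feature[bad], collapse = ", "))
  data.frame(feature = summary_t$feature, fold_change = fc)
}

#' Fold-change table for a study of recordings
#'
#' Computes, for every well and post-baseline timepoint, the per-feature
#' fold change of the well's weighted-mean features relative to that same
#' well's baseline. When a well has several pre-dose recordings their
#' electrode feature tables are pooled before summarising. Recordings whose
#' electrodes are all silenced by the activity filter are reported with `NA`
#' summaries rather than dropped.
#'
#' @param recordings List of [recording()] objects covering every well at
#'   baseline and at least one later timepoint.
#' @param params A [burst_params()].
#' @param min_spikes Active-electrode threshold (default 10).
#' @param weighting Passed to [well_summary()].
#' @param baseline_label Timepoint label(s) identifying pre-dose recordings.
#' @return Tidy data.frame: `device`, `well`, `condition`, `timepoint`,
#'   `feature`, `weighted_mean`, `weighted_sd`, `n_active_electrodes`,
#'   `fold_change` (baseline rows have fold change 1 by construction where
#'   defined).
#' @export
fold_change_table <- function(recordings, params = burst_params(),
                              min_spikes = 10, weighting = "count",
                              baseline_label = "baseline") {
  stopifnot(length(recordings) > 0)
  meta <- data.frame(
    device = vapply(recordings, `[[`, "", "device_id"),
    well = vapply(recordings, `[[`, "", "well_id"),
    condition = vapply(recordings, `[[`, "", "condition"),
    timepoint = vapply(recordings, `[[`, "", "timepoint"))
  wells <- unique(meta[c("device", "well", "condition")])
  no_baseline <- character()
  out <- list()
  for (r in seq_len(nrow(wells))) {
    sel <- meta$device == wells$device[r] & meta$well == wells$well[r]
    recs <- recordings[sel]
    tps <- meta$timepoint[sel]
    is_base <- tps %in% baseline_label
    if (!any(is_base)) {
      no_baseline <- c(no_baseline, wells$well[r])
      next
    }
    feats <- lapply(recs, function(rc)
      recording_features(filter_active_electrodes(rc, min_spikes), params))
    base_feat <- do.call(rbind, feats[is_base]) # pool pre-dose sessions
    base_sum <- summarise_features(base_feat, weighting)
    for (k in seq_along(recs)) {
      s <- summarise_features(feats[[k]], weighting)
      fc <- suppressWarnings(fold_change(s, base_sum))
      out[[length(out) + 1L]] <- data.frame(
        device = wells$device[r], well = wells$well[r],
        condition = wells$condition[r], timepoint = tps[k],
        s, fc["fold_change"])
    }
  }
  if (length(no_baseline))
    stop("wells without a baseline recording: ",
         paste(unique(no_baseline), collapse = ", "))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
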