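#' Network model for simulated MEA recordings
#'
#' Generative model of well-level spiking used to exercise the analysis
#' pipeline end to end: electrodes fire sparse independent Poisson
#' background spikes, and on top of that take part in coordinated
#' network-burst events. Each community follows its own Poisson event
#' stream of rate `burst_event_rate`; a fraction `event_sharing` of events
#' is common to all communities (culture-wide network bursts), the rest are
#' community-private. The number of spikes per burst is drawn once per
#' event, so electrodes joining the same event emit size-matched bursts
#' offset only by their Gaussian start jitter ("tight" electrodes a few
#' milliseconds, "loose" tens of milliseconds) and the per-event community
#' lag.
#'
#' This event-overlap structure reproduces the bimodal pairwise-synchrony
#' distribution of mature cultures: pairs within a community share
#' (essentially) their whole event stream and populate the high synchrony
#' mode near 0.9, while cross-community pairs share only the culture-wide
#' events and settle in the low mode around 0.3-0.5. Millisecond-scale
#' jitter contributes little here because the SPIKE-distance adapts to the
#' local interspike timescale; what separates the modes is which events a
#' pair has in common.
#'
#' @param n_electrodes Electrodes per well (default 59, an 8x8 grid minus
#'   ground and corners).
#' @param n_communities Number of communities partitioning the electrodes
#'   (default 2, near-equal blocks).
#' @param background_rate Background Poisson rate per electrode, Hz
#'   (default 0.005; mature bursty cultures fire mostly inside network
#'   bursts).
#' @param burst_event_rate Network-burst event rate per community, events
#'   per minute (default 15).
#' @param event_sharing Fraction of each community's events that is shared
#'   culture-wide, in `[0, 1]` (default 0.6); controls cross-community
#'   synchrony.
#' @param spikes_per_burst Integer range `c(min, max)`; per-event burst
#'   sizes are uniform on it.
#' @param intra_burst_isi Interspike interval inside a burst, seconds.
#' @param participation Probability an electrode joins a given event of its
#'   community (default 0.98).
#' @param tight_fraction Fraction of each community's electrodes in the
#'   tight jitter class.
#' @param jitter_tight,jitter_loose Per-electrode event jitter SD, seconds.
#' @param community_lag_sd SD of the per-event community lag, seconds.
#' @return A list of class `network_model` including the electrode
#'   `communities` partition and `jitter_class` assignment.
#' @export
network_model <- function(n_electrodes = 59, n_communities = 2,
                          background_rate = 0.005, burst_event_rate = 15,
                          event_sharing = 0.6,
                          spikes_per_burst = c(6, 15),
                          intra_burst_isi = 0.03, participation = 0.98,
                          tight_fraction = 0.5,
                          jitter_tight = 0.002, jitter_loose = 0.01,
                          community_lag_sd = 0.05) {
  stopifnot(n_electrodes >= 1, n_communities >= 1,
            n_communities <= n_electrodes,
            background_rate >= 0, burst_event_rate >= 0,
            event_sharing >= 0, event_sharing <= 1,
            length(spikes_per_burst) == 2, spikes_per_burst[1] >= 1,
            spikes_per_burst[2] >= spikes_per_burst[1],
            intra_burst_isi > 0, participation >= 0, participation <= 1,
            tight_fraction >= 0, tight_fraction <= 1,
            jitter_tight >= 0, jitter_loose >= 0, community_lag_sd >= 0)
  communities <- sort(rep_len(seq_len(n_communities), n_electrodes))
  jitter_class <- unlist(lapply(split(seq_len(n_electrodes), communities),
                                function(idx) {
    n_tight <- round(tight_fraction * length(idx))
    rep(c("tight", "loose"), c(n_tight, length(idx) - n_tight))
  }), use.names = FALSE)
  structure(list(
    n_electrodes = as.integer(n_electrodes),
    n_communities = as.integer(n_communities),
    communities = communities, jitter_class = jitter_class,
    background_rate = background_rate, burst_event_rate = burst_event_rate,
    event_sharing = event_sharing,
    spikes_per_burst = as.integer(spikes_per_burst),
    intra_burst_isi = intra_burst_isi, participation = participation,
    tight_fraction = tight_fraction,
    jitter_tight = jitter_tight, jitter_loose = jitter_loose,
    community_lag_sd = community_lag_sd), class = "network_model")
}

#' Expected per-electrode firing rate of a network model
#'
#' Closed form: `background_rate + participation * burst_event_rate / 60 *
#' mean(spikes_per_burst)`, all scaled by the activity multiplier.
#'
#' @param model A [network_model()].
#' @param multiplier Activity multiplier (dose effect).
#' @return Expected rate in Hz.
#' @export
expected_rate <- function(model, multiplier = 1) {
  stopifnot(inherits(model, "network_model"))
  multiplier * (model$background_rate +
    model$participation * model$burst_event_rate / 60 *
      mean(model$spikes_per_burst))
}

#' Simulate one well-level recording
#'
#' Draws the per-community event count from a Poisson process at
#' `multiplier * burst_event_rate`, designates a fixed `event_sharing`
#' fraction of those events as culture-wide (common times and burst sizes
#' across communities) and the rest as community-private,
#' assigns each event a burst size and each community a
#' Gaussian lag, lets each electrode join its community's events with
#' probability `participation` (emitting the event's burst size at regular
#' intra-burst ISIs, start jittered per its class), and superposes
#' background Poisson spikes at `multiplier * background_rate`. Spikes
#' outside `[0, duration)` are clipped; coincident spikes on one electrode
#' are deduplicated. Fully reproducible given `seed`.
#'
#' @param model A [network_model()].
#' @param duration Recording length in seconds (default 1800, a 30-minute
#'   session).
#' @param multiplier Non-negative activity multiplier applied to both the
#'   background and the event rate.
#' @param seed Integer seed.
#' @param device_id,well_id,condition,timepoint Metadata for the resulting
#'   recording.
#' @return A [recording()].
#' @examples
#' rec <- generate_recording(network_model(n_electrodes = 8), duration = 60,
#'                           seed = 1)
#' spike_counts(rec)
#' @export
generate_recording <- function(model, duration = 1800, multiplier = 1,
                               seed = 0, device_id = "sim", well_id = "well1",
                               condition = "0", timepoint = "baseline") {
  stopifnot(inherits(model, "network_model"), duration > 0)
  if (multiplier < 0) stop("multiplier must be non-negative")
  spikes <- with_seed(seed, {
    ev_rate <- multiplier * model$burst_event_rate / 60
    sizes <- model$spikes_per_burst[1]:model$spikes_per_burst[2]
    # each community sees n_events bursts; a fixed event_sharing fraction of
    # them is culture-wide, the rest community-private (the deterministic
    # split keeps the realized sharing fraction at its nominal value, so
    # cross-community synchrony does not drift from run to run)
    n_events <- stats::rpois(1, ev_rate * duration)
    n_shared <- round(model$event_sharing * n_events)
    shared_t <- stats::runif(n_shared, 0, duration)
    shared_n <- sample(sizes, n_shared, replace = TRUE)
    events <- lapply(seq_len(model$n_communities), function(comm) {
      n_priv <- n_events - n_shared
      t <- c(shared_t, stats::runif(n_priv, 0, duration))
      n <- c(shared_n, sample(sizes, n_priv, replace = TRUE))
      lag <- stats::rnorm(length(t), 0, model$community_lag_sd)
      list(t = t + lag, n = n)
    })
    lapply(seq_len(model$n_electrodes), function(e) {
      ev <- events[[model$communities[e]]]
      jsd <- if (model$jitter_class[e] == "tight") model$jitter_tight
             else model$jitter_loose
      burst_spk <- numeric()
      if (length(ev$t) > 0) {
        join <- which(stats::runif(length(ev$t)) < model$participation)
        if (length(join)) {
          starts <- ev$t[join] + stats::rnorm(length(join), 0, jsd)
          burst_spk <- unlist(lapply(seq_along(join), function(k)
            starts[k] + (seq_len(ev$n[join[k]]) - 1) * model$intra_burst_isi))
        }
      }
      n_bg <- stats::rpois(1, multiplier * model$background_rate * duration)
      tm <- sort(c(burst_spk, stats::runif(n_bg, 0, duration)))
      unique(tm[tm >= 0 & tm < duration])
    })
  })
  trains <- lapply(seq_along(spikes), function(e)
    spike_train(e - 1L, spikes[[e]], t_end = duration))
  recording(trains, duration = duration, device_id = device_id,
            well_id = well_id, condition = condition, timepoint = timepoint)
}

#' Dose-by-timepoint design of activity multipliers
#'
#' The default schedule emulates a sub-chronic exposure study: untreated
#' wells stay at multiplier 1 throughout; a low dose dips to 0.8 within the
#' first hour and recovers to 1 from 24 h on; a high dose is suppressed to
#' 0.2 at every post-dose timepoint. Baseline multipliers are 1 by
#' definition.
#'
#' @param conditions Dose labels (default `"0"`, `"0.01"`, `"10"`,
#'   micromolar).
#' @param timepoints Timepoint labels, first one the pre-dose baseline.
#' @param multipliers Numeric matrix `conditions x timepoints`; `NULL` gives
#'   the default schedule above (only defined for the default labels).
#' @return A list of class `dose_design`.
#' @export
dose_design <- function(conditions = c("0", "0.01", "10"),
                        timepoints = c("baseline", "30min", "1h", "24h",
                                       "48h", "72h", "96h"),
                        multipliers = NULL) {
  if (is.null(multipliers)) {
    stopifnot(identical(conditions, c("0", "0.01", "10")),
              identical(timepoints, c("baseline", "30min", "1h", "24h",
                                      "48h", "72h", "96h")))
    multipliers <- rbind(
      "0"    = rep(1, 7),
      "0.01" = c(1, 0.8, 0.8, 1, 1, 1, 1),
      "10"   = c(1, rep(0.2, 6)))
    colnames(multipliers) <- timepoints
  }
  multipliers <- as.matrix(multipliers)
  stopifnot(nrow(multipliers) == length(conditions),
            ncol(multipliers) == length(timepoints),
            all(multipliers >= 0), all(multipliers[, 1] == 1))
  dimnames(multipliers) <- list(conditions, timepoints)
  structure(list(conditions = conditions, timepoints = timepoints,
                 multipliers = multipliers), class = "dose_design")
}

#' Multiplier for a condition and timepoint
#' @param design A [dose_design()].
#' @param condition,timepoint Labels present in the design.
#' @return Scalar multiplier.
#' @export
dose_multiplier <- function(design, condition, timepoint) {
  stopifnot(inherits(design, "dose_design"))
  design$multipliers[as.character(condition), as.character(timepoint)]
}

#' Simulate a full dose-response study
#'
#' One recording per well and timepoint for every condition of the design.
#' Each well gets its own baseline character: its background and event rates
#' are scaled by fixed per-well factors drawn uniformly within
#' `1 +/- wobble` (default 10%), emulating the well-to-well variability that
#' makes baseline normalisation necessary. All randomness derives from the
#' master seed via a fixed per-(condition, well, timepoint) scheme.
#'
#' @param model A [network_model()].
#' @param design A [dose_design()].
#' @param n_wells_per_condition Wells per condition (default 6).
#' @param duration Recording length in seconds.
#' @param seed Master seed.
#' @param wobble Half-width of the per-well rate perturbation (fraction).
#' @return A list of class `mea_study`: `recordings` (list of
#'   [recording()]), `manifest` (data.frame of true multipliers, per-well
#'   factors and per-recording seeds), `model`, `design`.
#' @export
generate_study <- function(model, design = dose_design(),
                           n_wells_per_condition = 6, duration = 1800,
                           seed = 0, wobble = 0.1) {
  stopifnot(inherits(model, "network_model"), inherits(design, "dose_design"))
  recs <- list(); rows <- list()
  for (ci in seq_along(design$conditions)) {
    cond <- design$conditions[ci]
    for (w in seq_len(n_wells_per_condition)) {
      well <- sprintf("c%s_w%d", cond, w)
      wseed <- derive_seeds(seed, ci * 1000L + w)
      factors <- with_seed(wseed, stats::runif(2, 1 - wobble, 1 + wobble))
      wmodel <- model
      wmodel$background_rate <- model$background_rate * factors[1]
      wmodel$burst_event_rate <- model$burst_event_rate * factors[2]
      for (ti in seq_along(design$timepoints)) {
        tp <- design$timepoints[ti]
        mult <- dose_multiplier(design, cond, tp)
        rseed <- derive_seeds(seed, ci * 100000L + w * 100L + ti)
        recs[[length(recs) + 1L]] <- generate_recording(
          wmodel, duration = duration, multiplier = mult, seed = rseed,
          device_id = "sim", well_id = well, condition = cond, timepoint = tp)
        rows[[length(rows) + 1L]] <- data.frame(
          well = well, condition = cond, timepoint = tp, multiplier = mult,
          background_factor = factors[1], event_rate_factor = factors[2],
          seed = rseed)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(recordings = recs, manifest = manifest,
                 model = model, design = design), class = "mea_study")
}

#' @export
print.mea_study <- function(x, ...) {
  cat(sprintf("<mea_study> %d recordings: %d conditions x %d wells x %d timepoints\n",
              length(x$recordings), length(x$design$conditions),
              length(unique(x$manifest$well)) / length(x$design$conditions),
              length(x$design$timepoints)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits one recording file per well and timepoint (HDF5 or CSV dialect of
#' [write_recording()]) plus a `manifest.json` with the true simulation
#' parameters, for parameter-recovery analyses.
#'
#' @param study An `mea_study` from [generate_study()].
#' @param dir Output directory (created if missing).
#' @param format `"csv"` or `"hdf5"`.
#' @return Invisibly, the manifest with a `path` column added.
#' @export
write_study <- function(study, dir, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  stopifnot(inherits(study, "mea_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "csv") "csv" else "h5"
  paths <- vapply(study$recordings, function(rec) {
    p <- file.path(dir, sprintf("%s_%s.%s", rec$well_id, rec$timepoint, ext))
    write_recording(rec, p, format)
    p
  }, character(1))
  manifest <- cbind(study$manifest, path = paths)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
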