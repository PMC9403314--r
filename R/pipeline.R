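#' Run the full analysis over a set of recordings
#'
#' The end-to-end pipeline: silent-electrode filtering, burst detection,
#' per-electrode features, well-level weighted summaries, fold changes to
#' the well-matched baseline, and (optionally) pairwise normalised
#' synchrony, link classification and Louvain communities per recording.
#' Deterministic given the seed; no stage mutates its inputs.
#'
#' @param recordings List of [recording()] objects; every well must include
#'   a baseline recording.
#' @param burst_params A [burst_params()].
#' @param synchrony_params A [synchrony_params()]; its `seed` is combined
#'   with a per-recording index.
#' @param min_spikes Active-electrode threshold (default 10).
#' @param strong_threshold Strong-link cutoff (default 0.7).
#' @param weighting Electrode weighting for summaries, see [well_summary()].
#' @param compute_synchrony Whether to run the synchrony/network stage
#'   (the expensive stage; features and fold changes always run).
#' @param synchrony_timepoints Timepoint labels to run synchrony on;
#'   `NULL` means all.
#' @param louvain_seed Seed for community detection.
#' @return A list of class `study_results`: `features` (the tidy
#'   fold-change table), `dropped_recordings` (wells/timepoints whose
#'   electrodes were all silenced), `synchrony` (long link table per
#'   recording with strong/weak labels), `device_synchrony` (per-recording
#'   average link synchrony), `communities` (electrode-community table),
#'   `provenance` (parameters and seeds of the run).
#' @export
run_study <- function(recordings, burst_params = meanet::burst_params(),
                      synchrony_params = meanet::synchrony_params(),
                      min_spikes = 10, strong_threshold = 0.7,
                      weighting = "count", compute_synchrony = TRUE,
                      synchrony_timepoints = NULL, louvain_seed = 0) {
  stopifnot(is.list(recordings), length(recordings) > 0)
  features <- fold_change_table(recordings, burst_params,
                                min_spikes = min_spikes,
                                weighting = weighting)
  active_counts <- vapply(recordings, function(r)
    length(filter_active_electrodes(r, min_spikes)$trains), integer(1))
  dropped <- data.frame(
    well = vapply(recordings, `[[`, "", "well_id"),
    condition = vapply(recordings, `[[`, "", "condition"),
    timepoint = vapply(recordings, `[[`, "", "timepoint"),
    n_active_electrodes = active_counts)[active_counts == 0, ]
  rownames(dropped) <- NULL

  sync_tab <- dev_tab <- comm_tab <- NULL
  if (compute_synchrony) {
    sync_rows <- list(); dev_rows <- list(); comm_rows <- list()
    for (i in seq_along(recordings)) {
      rec <- recordings[[i]]
      if (!is.null(synchrony_timepoints) &&
          !(rec$timepoint %in% synchrony_timepoints)) next
      act <- filter_active_electrodes(rec, min_spikes)
      if (length(act$trains) < 2) next
      sp <- synchrony_params
      sp$seed <- derive_seeds(synchrony_params$seed, i)
      m <- pairwise_matrix(act, sp)
      links <- classify_links(m, strong_threshold)
      part <- louvain_partition(m, seed = louvain_seed)
      key <- data.frame(well = rec$well_id, condition = rec$condition,
                        timepoint = rec$timepoint)
      sync_rows[[length(sync_rows) + 1L]] <- cbind(key, links)
      dev_rows[[length(dev_rows) + 1L]] <- cbind(
        key, data.frame(mean_synchrony = device_average_synchrony(m),
                        n_links = nrow(links),
                        modularity = part$modularity,
                        n_communities = part$n_communities))
      comm_rows[[length(comm_rows) + 1L]] <- cbind(
        key, data.frame(electrode = electrode_ids(act),
                        community = as.integer(part$membership)))
    }
    bindr <- function(x) if (length(x)) {
      out <- do.call(rbind, x); rownames(out) <- NULL; out
    }
    sync_tab <- bindr(sync_rows)
    dev_tab <- bindr(dev_rows)
    comm_tab <- bindr(comm_rows)
  }
  structure(list(
    features = features, dropped_recordings = dropped,
    synchrony = sync_tab, device_synchrony = dev_tab, communities = comm_tab,
    provenance = list(
      n_recordings = length(recordings),
      burst_params = unclass(burst_params),
      synchrony_params = unclass(synchrony_params),
      min_spikes = min_spikes, strong_threshold = strong_threshold,
      weighting = weighting, louvain_seed = louvain_seed,
      package_version = as.character(utils::packageVersion("meanet")))),
    class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results> %d recordings, %d feature rows%s\n",
              x$provenance$n_recordings, nrow(x$features),
              if (!is.null(x$synchrony))
                sprintf(", %d synchrony links", nrow(x$synchrony)) else ""))
  invisible(x)
}

#' Write study results as tidy CSV tables and a run manifest
#'
#' Emits `features.csv` (well x timepoint x feature summaries and fold
#' changes), `synchrony_links.csv`, `device_synchrony.csv`,
#' `communities.csv`, a pooled `synchrony_histogram.csv` per condition and
#' timepoint, and `run_manifest.json` describing parameters and seeds.
#' Empty stages produce headers-only files.
#'
#' @param results A `study_results` from [run_study()].
#' @param outdir Output directory (created if missing).
#' @param n_bins Bins for the pooled synchrony histograms.
#' @return Invisibly, the vector of written paths.
#' @export
report_study <- function(results, outdir, n_bins = 25) {
  stopifnot(inherits(results, "study_results"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(results$features, "features.csv")
  empty_links <- data.frame(well = character(), condition = character(),
                            timepoint = character(), elec_i = integer(),
                            elec_j = integer(), synchrony = numeric(),
                            strength = character())
  wr(if (is.null(results$synchrony)) empty_links else results$synchrony,
     "synchrony_links.csv")
  if (!is.null(results$device_synchrony))
    wr(results$device_synchrony, "device_synchrony.csv")
  if (!is.null(results$communities))
    wr(results$communities, "communities.csv")
  if (!is.null(results$synchrony) && nrow(results$synchrony)) {
    grp <- split(results$synchrony,
                 results$synchrony[c("condition", "timepoint")], drop = TRUE)
    hist_tab <- do.call(rbind, lapply(names(grp), function(g) {
      d <- synchrony_distribution(grp[[g]]$synchrony, n_bins = n_bins)
      cbind(condition = grp[[g]]$condition[1],
            timepoint = grp[[g]]$timepoint[1], d$histogram)
    }))
    wr(hist_tab, "synchrony_histogram.csv")
  }
  manifest_path <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(results$provenance, manifest_path,
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, manifest_path)
  invisible(paths)
}
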