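#' Read a spike recording from HDF5 or CSV
#'
#' Two on-disk dialects are supported.
#'
#' \describe{
#'   \item{hdf5}{Group `/spikes` holds one 1-D float64 dataset per electrode
#'     named `e<k>`; root attributes `duration_s`, `device_id`, `well_id`,
#'     `condition`, `timepoint`. Read and written through a bundled Python
#'     helper built on h5py, exchanging values at full float64 precision.}
#'   \item{csv}{Header `electrode,time_s`, one spike per row. Duration and
#'     metadata come from a JSON sidecar (`<path>.json`) or the `duration`
#'     argument, which takes precedence.}
#' }
#'
#' Electrodes present in the file but holding no spikes are kept as
#' zero-length trains, so downstream activity filters see them.
#'
#' @param path File to read.
#' @param format `"hdf5"` or `"csv"`; default guessed from the extension.
#' @param duration Recording length in seconds; required for CSV files
#'   without a sidecar, ignored for HDF5.
#' @return A [recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "hdf5", "csv"),
                           duration = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "csv"
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         hdf5 = read_recording_h5(path),
         csv  = read_recording_csv(path, duration))
}

read_recording_csv <- function(path, duration = NULL) {
  df <- utils::read.csv(path, colClasses = c("integer", "numeric"))
  if (!identical(names(df), c("electrode", "time_s")))
    stop("malformed CSV ", path, ": expected header 'electrode,time_s', got '",
         paste(names(df), collapse = ","), "'")
  meta <- list(device_id = "device1", well_id = "well1",
               condition = "0", timepoint = "baseline")
  declared <- integer() # zero-spike electrodes appear only in the sidecar
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta[names(sc)[names(sc) %in% names(meta)]] <-
      sc[names(sc) %in% names(meta)]
    if (is.null(duration) && !is.null(sc$duration_s))
      duration <- as.numeric(sc$duration_s)
    if (!is.null(sc$electrodes)) declared <- as.integer(sc$electrodes)
  }
  if (is.null(duration))
    stop("CSV dialect carries no duration: supply `duration` or a '", sidecar,
         "' sidecar with field duration_s")
  ids <- sort(unique(c(df$electrode, declared)))
  trains <- lapply(ids, function(k) {
    tm <- sort(df$time_s[df$electrode == k])
    if (anyDuplicated(tm)) stop("non-increasing spike times for electrode ", k,
                                " in ", path)
    spike_train(k, tm, t_end = duration)
  })
  recording(trains, duration = duration, device_id = meta$device_id,
            well_id = meta$well_id, condition = meta$condition,
            timepoint = meta$timepoint)
}

read_recording_h5 <- function(path) {
  json <- tempfile(fileext = ".json")
  on.exit(unlink(json), add = TRUE)
  h5_bridge("dump", path, json)
  rec <- jsonlite::read_json(json, simplifyVector = TRUE)
  ids <- sort(as.integer(sub("^e", "", names(rec$spikes))))
  trains <- lapply(ids, function(k) {
    tm <- as.numeric(rec$spikes[[paste0("e", k)]])
    spike_train(k, sort(tm), t_end = rec$duration_s)
  })
  recording(trains, duration = rec$duration_s, device_id = rec$device_id,
            well_id = rec$well_id, condition = rec$condition,
            timepoint = rec$timepoint)
}

h5_bridge <- function(cmd, from, to) {
  helper <- system.file("python", "h5io.py", package = "meanet", mustWork = TRUE)
  out <- suppressWarnings(
    system2("python", c(shQuote(helper), cmd, shQuote(from), shQuote(to)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("HDF5 bridge failed on ", from, ": ", paste(out, collapse = "\n"))
  invisible(NULL)
}

#' Write a spike recording to HDF5 or CSV
#'
#' Values round-trip exactly: `read_recording(write_recording(rec, p), p)`
#' reproduces every spike time bit-identically in both formats. Zero-spike
#' electrodes are written as empty datasets (HDF5) or merely recorded in the
#' sidecar electrode list (CSV), never dropped. The CSV writer always emits
#' the `<path>.json` sidecar with duration and metadata.
#'
#' @param rec A [recording()].
#' @param path Output file.
#' @param format `"hdf5"` or `"csv"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "hdf5", "csv")) {
  stopifnot(inherits(rec, "mea_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "csv"
  if (format == "csv") {
    n <- spike_counts(rec)
    df <- data.frame(
      electrode = rep(electrode_ids(rec), n),
      time_s = unlist(lapply(rec$trains, `[[`, "times"), use.names = FALSE))
    utils::write.csv(format_full(df), path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(duration_s = rec$duration, device_id = rec$device_id,
           well_id = rec$well_id, condition = rec$condition,
           timepoint = rec$timepoint, electrodes = electrode_ids(rec)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    json <- tempfile(fileext = ".json")
    on.exit(unlink(json), add = TRUE)
    spikes <- lapply(rec$trains, function(tr) I(tr$times))
    # 17 significant digits: float64 survives the JSON bridge exactly
    jsonlite::write_json(
      list(duration_s = rec$duration, device_id = rec$device_id,
           well_id = rec$well_id, condition = rec$condition,
           timepoint = rec$timepoint, spikes = spikes),
      json, auto_unbox = TRUE, digits = I(17))
    h5_bridge("load", json, path)
  }
  invisible(path)
}

# full-precision decimal formatting so CSV round-trips float64 exactly
format_full <- function(df) {
  df$time_s <- sprintf("%.17g", df$time_s)
  df
}

#' Threshold spike detection from a raw voltage trace
#'
#' Detects spikes as excursions beyond `threshold_multiplier` times a robust
#' estimate of the baseline noise standard deviation
#' (`median(|x|) / 0.6745`, the usual MAD-based estimator, so large spikes do
#' not inflate their own threshold). A detection is placed at the first
#' sample of each crossing; crossings closer than `dead_time` to the previous
#' detection are collapsed into it.
#'
#' @param trace Numeric vector of voltage samples (baseline-subtracted).
#' @param fs Sampling frequency in Hz.
#' @param threshold_multiplier Threshold in units of noise SD; default 6.5.
#' @param polarity `"negative"` (default; extracellular action potentials are
#'   negative-going on MEAs), `"positive"`, or `"both"`.
#' @param dead_time Minimum separation between detections in seconds
#'   (default 1 ms).
#' @return Sorted numeric vector of spike times in seconds, within
#'   `[0, length(trace)/fs)`.
#' @examples
#' set.seed(1)
#' x <- rnorm(10000)
#' x[5000] <- -30
#' detect_spikes(x, fs = 10000)
#' @export
detect_spikes <- function(trace, fs, threshold_multiplier = 6.5,
                          polarity = c("negative", "positive", "both"),
                          dead_time = 1e-3) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(trace), length(trace) >= 2, fs > 0,
            threshold_multiplier > 0, dead_time >= 0)
  noise_sd <- stats::median(abs(trace)) / 0.6745
  if (noise_sd == 0) {
    warning("constant trace: noise SD is zero, no spikes detected")
    return(numeric())
  }
  thr <- threshold_multiplier * noise_sd
  over <- switch(polarity,
                 negative = trace < -thr,
                 positive = trace > thr,
                 both     = abs(trace) > thr)
  idx <- which(over & !c(FALSE, over[-length(over)])) # first sample of each run
  if (!length(idx)) return(numeric())
  t <- (idx - 1) / fs
  keep <- c(TRUE, diff(t) >= dead_time)
  # collapse chains: re-scan because dead time is relative to the last KEPT spike
  if (!all(keep)) {
    last <- t[1]
    keep <- logical(length(t)); keep[1] <- TRUE
    for (i in seq_along(t)[-1]) {
      if (t[i] - last >= dead_time) {
        keep[i] <- TRUE
        last <- t[i]
      }
    }
  }
  t[keep]
}

#' Drop silent electrodes from a recording
#'
#' Removes electrodes with fewer than `min_spikes` spikes (default 10,
#' i.e. electrodes with <10 spikes over the session are considered silent),
#' leaving metadata untouched. Idempotent, and monotone in `min_spikes`.
#'
#' @param rec A [recording()].
#' @param min_spikes Minimum spike count for an electrode to be kept.
#' @return A new [recording()] containing only the active electrodes (possibly
#'   none).
#' @export
filter_active_electrodes <- function(rec, min_spikes = 10) {
  stopifnot(inherits(rec, "mea_recording"), min_spikes >= 0)
  keep <- spike_counts(rec) >= min_spikes
  recording(unname(rec$trains[keep]), duration = rec$duration,
            device_id = rec$device_id, well_id = rec$well_id,
            condition = rec$condition, timepoint = rec$timepoint)
}
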