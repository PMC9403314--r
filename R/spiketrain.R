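#' Spike train for one electrode
#'
#' A spike train is a strictly increasing vector of spike times (seconds,
#' measured from the start of the recording) observed on one electrode over
#' the half-open window `[t_start, t_end)`.
#'
#' @param electrode_id Non-negative integer electrode index.
#' @param times Numeric vector of spike times in seconds, strictly increasing,
#'   all within `[t_start, t_end)`.
#' @param t_start,t_end Recording window in seconds, `t_end > t_start`.
#' @return An object of class `spike_train`.
#' @examples
#' st <- spike_train(0, c(0.1, 0.25, 0.9), t_end = 1)
#' n_spikes(st)
#' @export
spike_train <- function(electrode_id, times = numeric(), t_start = 0, t_end) {
  electrode_id <- as.integer(electrode_id)
  times <- as.numeric(times)
  stopifnot(length(electrode_id) == 1L, !is.na(electrode_id), electrode_id >= 0L)
  if (!is.numeric(t_start) || !is.numeric(t_end) || t_end <= t_start)
    stop("t_end must be greater than t_start")
  if (anyNA(times)) stop("spike times contain NA")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("spike times must be strictly increasing (electrode ", electrode_id, ")")
  if (length(times) && (times[1L] < t_start || times[length(times)] >= t_end))
    stop("spike times must lie in [t_start, t_end) (electrode ", electrode_id, ")")
  structure(
    list(electrode_id = electrode_id, times = times,
         t_start = as.numeric(t_start), t_end = as.numeric(t_end)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> electrode %d: %d spikes in [%g, %g) s\n",
              x$electrode_id, length(x$times), x$t_start, x$t_end))
  invisible(x)
}

#' Number of spikes in a train
#' @param x A `spike_train`.
#' @return Integer spike count.
#' @export
n_spikes <- function(x) {
  stopifnot(inherits(x, "spike_train"))
  length(x$times)
}

#' Well-level recording: a set of spike trains plus metadata
#'
#' A recording bundles the spike trains of all electrodes of one well for one
#' session, together with the metadata used downstream (device, well, dose
#' condition, timepoint, duration). All trains share the window
#' `[0, duration)` and electrode ids are unique.
#'
#' @param trains List of [spike_train()] objects.
#' @param duration Recording length in seconds (positive).
#' @param device_id,well_id Character labels.
#' @param condition Dose label, e.g. `"0"`, `"0.01"`, `"10"` (micromolar) or
#'   any free string.
#' @param timepoint Timepoint label, e.g. `"baseline"`, `"30min"`, `"96h"`.
#' @return An object of class `mea_recording`.
#' @examples
#' rec <- recording(list(spike_train(0, c(0.1, 0.2), t_end = 1)), duration = 1)
#' spike_counts(rec)
#' @export
recording <- function(trains, duration, device_id = "device1", well_id = "well1",
                      condition = "0", timepoint = "baseline") {
  duration <- as.numeric(duration)
  if (!length(duration) == 1L || is.na(duration) || duration <= 0)
    stop("duration must be a positive scalar (seconds)")
  stopifnot(is.list(trains))
  for (tr in trains) {
    if (!inherits(tr, "spike_train")) stop("trains must be spike_train objects")
    if (tr$t_start != 0 || tr$t_end != duration)
      stop("all trains must share the window [0, duration)")
  }
  ids <- vapply(trains, function(tr) tr$electrode_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate electrode ids")
  trains <- trains[order(ids)]
  if (length(trains)) names(trains) <- paste0("e", sort(ids))
  structure(
    list(trains = trains, duration = duration,
         device_id = as.character(device_id), well_id = as.character(well_id),
         condition = as.character(condition), timepoint = as.character(timepoint)),
    class = "mea_recording"
  )
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "<mea_recording> %s/%s  condition %s uM, %s\n  %d electrodes, %d spikes, %g s\n",
    x$device_id, x$well_id, x$condition, x$timepoint,
    length(x$trains), sum(spike_counts(x)), x$duration))
  invisible(x)
}

#' Per-electrode spike counts of a recording
#' @param rec A `mea_recording`.
#' @return Named integer vector (names `e<k>`).
#' @export
spike_counts <- function(rec) {
  stopifnot(inherits(rec, "mea_recording"))
  vapply(rec$trains, function(tr) length(tr$times), integer(1))
}

#' Electrode ids of a recording
#' @param rec A `mea_recording`.
#' @return Integer vector of electrode ids, ascending.
#' @export
electrode_ids <- function(rec) {
  stopifnot(inherits(rec, "mea_recording"))
  vapply(rec$trains, function(tr) tr$electrode_id, integer(1))
}
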