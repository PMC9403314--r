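#' Parameters for surrogate-normalised synchrony
#'
#' @param n_surrogates Number of surrogate train pairs per electrode pair
#'   (default 20).
#' @param surrogate_model Only `"rate_matched_poisson"`: surrogates are
#'   homogeneous Poisson trains with the same duration and the same spike
#'   counts as the observed pair.
#' @param grid_dt Grid step for the dissimilarity-profile integration,
#'   seconds (default 1 ms).
#' @param seed Master seed; every surrogate draw is derived from it, so
#'   results are reproducible.
#' @return A list of class `synchrony_params`.
#' @export
synchrony_params <- function(n_surrogates = 20,
                             surrogate_model = "rate_matched_poisson",
                             grid_dt = 1e-3, seed = 0) {
  stopifnot(n_surrogates >= 1, grid_dt > 0,
            surrogate_model == "rate_matched_poisson")
  structure(list(n_surrogates = as.integer(n_surrogates),
                 surrogate_model = surrogate_model,
                 grid_dt = grid_dt, seed = as.integer(seed)),
            class = "synchrony_params")
}

#' SPIKE-distance between two spike trains
#'
#' Time-resolved, time-scale-free dissimilarity in `[0, 1]`; 0 for identical
#' trains. At each time `t` the instantaneous dissimilarity `S(t)` is built,
#' for each train, from the distances of its corner spikes (previous spike
#' `t_P`, following spike `t_F`) to the nearest spike of the other train,
#' interpolated by the position of `t` inside the local interspike interval:
#' `S_n(t) = (dt_P x_F + dt_F x_P) / x_ISI`. The two profiles are combined,
#' weighted by the other train's local ISI, and normalised by the squared
#' mean local ISI:
#' `S(t) = (S_1 x_ISI2 + S_2 x_ISI1) / (2 <x_ISI>^2)`.
#' The reported distance is the time average of `S(t)`, evaluated as a
#' midpoint Riemann sum on a uniform grid of step `grid_dt`. Auxiliary
#' spikes at the window edges provide the usual edge correction.
#'
#' @param a,b [spike_train()] objects on the same window, each with at least
#'   one spike.
#' @param grid_dt Integration grid step, seconds.
#' @return Scalar dissimilarity in `[0, 1]`.
#' @examples
#' a <- spike_train(0, c(0.1, 0.5, 0.9), t_end = 1)
#' spike_distance(a, a) # identical trains: 0
#' @export
spike_distance <- function(a, b, grid_dt = 1e-3) {
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"),
            grid_dt > 0)
  if (a$t_start != b$t_start || a$t_end != b$t_end)
    stop("trains must share the same window")
  if (!length(a$times) || !length(b$times))
    stop("empty train: apply filter_active_electrodes() before computing synchrony")
  t_len <- a$t_end - a$t_start
  aa <- aux_edges(a$times - a$t_start, t_len)
  bb <- aux_edges(b$times - b$t_start, t_len)
  spike_dist_grid_cpp(aa, bb, t_len, grid_dt)
}

# add auxiliary edge spikes at 0 and t_len (deduplicated)
aux_edges <- function(times, t_len) {
  unique(c(0, times, t_len))
}

#' Raw synchrony: one minus the SPIKE-distance
#'
#' @inheritParams spike_distance
#' @return Similarity in `[0, 1]`; 1 means perfect synchrony, 0 complete
#'   asynchrony.
#' @export
raw_synchrony <- function(a, b, grid_dt = 1e-3) {
  1 - spike_distance(a, b, grid_dt)
}

#' Surrogate-normalised synchrony
#'
#' The SPIKE-distance is biased towards smaller distances (higher apparent
#' synchrony) for denser spike trains. To compensate, the observed distance
#' is normalised by the mean SPIKE-distance of randomly generated surrogate
#' pairs: homogeneous Poisson trains with the same duration and the same
#' spike counts as the observed pair. The score is
#' `clip(1 - D_obs / D_rand, 0, 1)`: identical trains score exactly 1
#' (numerator zero) and rate-matched independent trains score close to 0 in
#' expectation, at any firing rate.
#'
#' @inheritParams spike_distance
#' @param params A [synchrony_params()].
#' @param pair_index Integer folded into the surrogate seed so each electrode
#'   pair of a matrix gets its own reproducible surrogate draw.
#' @return Normalised synchrony in `[0, 1]` (`NA` with a warning in the
#'   degenerate case `D_rand = 0`).
#' @export
normalized_synchrony <- function(a, b, params = synchrony_params(),
                                 pair_index = 0L) {
  stopifnot(inherits(params, "synchrony_params"))
  d_obs <- spike_distance(a, b, params$grid_dt)
  if (d_obs == 0) return(1)
  d_rand <- surrogate_distance(length(a$times), length(b$times),
                               a$t_end - a$t_start, params, pair_index)
  if (d_rand == 0) {
    warning("degenerate surrogate distance of zero; synchrony undefined")
    return(NA_real_)
  }
  min(1, max(0, 1 - d_obs / d_rand))
}

surrogate_distance <- function(n_a, n_b, t_len, params, pair_index = 0L) {
  seeds <- derive_seeds(params$seed, 1000L + pair_index, params$n_surrogates)
  mean(vapply(seeds, function(s) {
    set.seed(s)
    sa <- aux_edges(sort(stats::runif(n_a, 0, t_len)), t_len)
    sb <- aux_edges(sort(stats::runif(n_b, 0, t_len)), t_len)
    spike_dist_grid_cpp(sa, sb, t_len, params$grid_dt)
  }, numeric(1)))
}

#' Pairwise normalised synchrony matrix of a recording
#'
#' Computes [normalized_synchrony()] for every unordered pair of electrodes.
#' Surrogate draws are seeded per pair from the master seed, so the matrix is
#' deterministic given `params$seed` and does not depend on electrode order.
#'
#' @param rec A [recording()], already active-filtered; at least two
#'   electrodes (fewer yields an empty matrix with a warning).
#' @param params A [synchrony_params()].
#' @return A list of class `synchrony_matrix`: `electrode_ids` and `values`
#'   (symmetric matrix in `[0, 1]`, unit diagonal).
#' @export
pairwise_matrix <- function(rec, params = synchrony_params()) {
  stopifnot(inherits(rec, "mea_recording"))
  ids <- electrode_ids(rec)
  k <- length(ids)
  m <- matrix(if (k) 1 else numeric(), k, k,
              dimnames = list(paste0("e", ids), paste0("e", ids)))
  if (k < 2) {
    warning("fewer than 2 electrodes: empty synchrony matrix")
    return(structure(list(electrode_ids = ids, values = m),
                     class = "synchrony_matrix"))
  }
  pair <- 0L
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    pair <- pair + 1L
    v <- normalized_synchrony(rec$trains[[i]], rec$trains[[j]],
                              params, pair_index = pair)
    m[i, j] <- m[j, i] <- v
  }
  structure(list(electrode_ids = ids, values = m), class = "synchrony_matrix")
}

#' @export
print.synchrony_matrix <- function(x, ...) {
  k <- length(x$electrode_ids)
  vals <- upper_links(x)
  cat(sprintf("<synchrony_matrix> %d electrodes, %d links%s\n", k,
              length(vals),
              if (length(vals)) sprintf(", mean %.3f", mean(vals, na.rm = TRUE))
              else ""))
  invisible(x)
}

# upper-triangle link values of a synchrony matrix
upper_links <- function(m) {
  stopifnot(inherits(m, "synchrony_matrix"))
  m$values[upper.tri(m$values)]
}

#' Long-format link table of a synchrony matrix
#'
#' @param m A `synchrony_matrix` from [pairwise_matrix()].
#' @return data.frame `elec_i`, `elec_j`, `synchrony` (one row per unordered
#'   pair, `elec_i < elec_j`).
#' @export
synchrony_edges <- function(m) {
  stopifnot(inherits(m, "synchrony_matrix"))
  k <- length(m$electrode_ids)
  if (k < 2)
    return(data.frame(elec_i = integer(), elec_j = integer(),
                      synchrony = numeric()))
  idx <- which(upper.tri(m$values), arr.ind = TRUE)
  data.frame(elec_i = m$electrode_ids[idx[, 1]],
             elec_j = m$electrode_ids[idx[, 2]],
             synchrony = m$values[idx])
}
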