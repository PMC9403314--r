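# Independent reference implementations and fixture generators used as
# oracles. These are written directly from the definitions and kept separate
# from the package's code paths.

# Dense-grid reference for the SPIKE dissimilarity, vectorised plain R.
# a, b: raw spike times (no edge spikes); t_len: window length.
ref_spike_distance <- function(a, b, t_len, dt = 1e-4) {
  a <- unique(c(0, a, t_len))
  b <- unique(c(0, b, t_len))
  near_a <- vapply(a, function(s) min(abs(b - s)), numeric(1))
  near_b <- vapply(b, function(s) min(abs(a - s)), numeric(1))
  m <- max(1L, round(t_len / dt))
  tg <- (seq_len(m) - 0.5) * (t_len / m)
  ia <- findInterval(tg, a)
  ib <- findInterval(tg, b)
  xP1 <- tg - a[ia];  xF1 <- a[ia + 1] - tg;  isi1 <- a[ia + 1] - a[ia]
  xP2 <- tg - b[ib];  xF2 <- b[ib + 1] - tg;  isi2 <- b[ib + 1] - b[ib]
  S1 <- (near_a[ia] * xF1 + near_a[ia + 1] * xP1) / isi1
  S2 <- (near_b[ib] * xF2 + near_b[ib + 1] * xP2) / isi2
  S <- (S1 * isi2 + S2 * isi1) / (2 * ((isi1 + isi2) / 2)^2)
  mean(S)
}

# Literal four-step max-interval reference: (1) open candidate at
# ISI <= max_begin, (2) extend while ISI <= max_end, (3) merge gaps
# < min_ibi, (4) drop candidates under the size/duration thresholds.
# Returns a matrix of index spans (first, last), 0 rows if none.
ref_max_interval <- function(times, p) {
  n <- length(times)
  if (n < 2) return(matrix(integer(), 0, 2))
  isi <- diff(times)
  cand <- list()
  i <- 1L
  while (i <= n - 1L) {
    if (isi[i] <= p$max_begin_isi) {
      j <- i + 1L
      while (j <= n - 1L && isi[j] <= p$max_end_isi) j <- j + 1L
      cand[[length(cand) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) return(matrix(integer(), 0, 2))
  merged <- list(cand[[1L]])
  for (c in cand[-1L]) {
    prev <- merged[[length(merged)]]
    if (times[c[1L]] - times[prev[2L]] < p$min_ibi)
      merged[[length(merged)]][2L] <- c[2L]
    else merged[[length(merged) + 1L]] <- c
  }
  spans <- do.call(rbind, merged)
  keep <- (spans[, 2] - spans[, 1] + 1L) >= p$min_spikes &
    (times[spans[, 2]] - times[spans[, 1]]) >= p$min_duration
  spans[keep, , drop = FALSE]
}

# modularity from the summation form: Q = (1/2W) sum_ij (A_ij - k_i k_j / 2W)
# over pairs in the same community (diagonal A_ii = 0 included in the null).
ref_modularity <- function(A, membership) {
  diag(A) <- 0
  W2 <- sum(A)             # = 2W
  if (W2 == 0) return(0)
  k <- rowSums(A)
  same <- outer(membership, membership, "==")
  sum((A - outer(k, k) / W2)[same]) / W2
}

# every set partition of n elements, as a list of membership vectors
all_partitions <- function(n) {
  out <- list()
  recurse <- function(memb, next_id) {
    i <- length(memb) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- memb
      return(invisible())
    }
    for (g in seq_len(next_id))
      recurse(c(memb, g), max(next_id, g + 1L))
  }
  recurse(integer(), 1L)
  out
}

ref_best_modularity <- function(A) {
  parts <- all_partitions(nrow(A))
  max(vapply(parts, function(p) ref_modularity(A, p), numeric(1)))
}

# homogeneous Poisson train on [0, t_len) with expected count rate * t_len
poisson_times <- function(rate, t_len) {
  unique(sort(stats::runif(stats::rpois(1, rate * t_len), 0, t_len)))
}

poisson_train <- function(rate, t_len, id = 0) {
  spike_train(id, poisson_times(rate, t_len), t_end = t_len)
}

# Poisson background with planted regular bursts, for burst-detector stress
mixed_train <- function(t_len = 60, bg_rate = 0.5, n_bursts = 4) {
  t <- poisson_times(bg_rate, t_len)
  for (k in seq_len(n_bursts)) {
    nspk <- sample(2:15, 1)
    isi <- stats::runif(1, 0.02, 0.25)
    t0 <- stats::runif(1, 0, t_len - nspk * isi)
    t <- c(t, t0 + (seq_len(nspk) - 1) * isi)
  }
  unique(sort(t[t >= 0 & t < t_len]))
}

# symmetric planted two-block weight matrix in [0, 1]
planted_matrix <- function(n = 16, w_in = c(0.75, 0.95), w_out = c(0.15, 0.35)) {
  memb <- rep(1:2, length.out = n)
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- if (memb[i] == memb[j]) stats::runif(1, w_in[1], w_in[2])
         else stats::runif(1, w_out[1], w_out[2])
    A[i, j] <- A[j, i] <- r
  }
  list(A = A, membership = memb)
}

# recording with prescribed per-electrode spike counts (regular trains)
counts_recording <- function(counts, duration = 60) {
  trains <- lapply(seq_along(counts), function(i) {
    n <- counts[i]
    tm <- if (n > 0) seq(0.5, duration - 0.5, length.out = n) else numeric()
    spike_train(i - 1L, tm, t_end = duration)
  })
  recording(trains, duration = duration)
}

# stratified electrode subset of a default network model: nper electrodes,
# nper/4 tight and nper/4 loose per community
stratified_subset <- function(model, nper) {
  sort(unlist(lapply(split(seq_len(model$n_electrodes), model$communities),
                     function(idx) {
    cls <- model$jitter_class[idx]
    c(idx[cls == "tight"][seq_len(nper / 4)],
      idx[cls == "loose"][seq_len(nper / 4)])
  })))
}

subset_recording <- function(rec, idx) {
  recording(unname(rec$trains[idx]), duration = rec$duration,
            device_id = rec$device_id, well_id = rec$well_id,
            condition = rec$condition, timepoint = rec$timepoint)
}
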