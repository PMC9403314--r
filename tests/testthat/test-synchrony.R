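test_that("identical trains are at zero distance and perfect synchrony", {
  set.seed(1)
  a <- poisson_train(5, 60)
  expect_identical(spike_distance(a, a), 0)
  expect_identical(raw_synchrony(a, a), 1)
  expect_identical(normalized_synchrony(a, a), 1)
  # at any rate
  d <- poisson_train(40, 60)
  expect_identical(normalized_synchrony(d, d), 1)
})

test_that("distance is symmetric, bounded, and translation-insensitive", {
  set.seed(2)
  for (rep in 1:300) {
    t_len <- 5
    a <- poisson_train(runif(1, 1, 30), t_len)
    b <- poisson_train(runif(1, 1, 30), t_len, 1)
    if (!length(a$times) || !length(b$times)) next
    d <- spike_distance(a, b)
    expect_identical(d, spike_distance(b, a))
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
  # jointly shifting both trains inside the window changes only edge terms
  set.seed(3)
  t0 <- sort(runif(100, 5, 50)); t1 <- sort(runif(80, 5, 50))
  sh <- 4
  d_orig <- spike_distance(spike_train(0, t0, t_end = 60),
                           spike_train(1, t1, t_end = 60))
  d_shift <- spike_distance(spike_train(0, t0 + sh, t_end = 60),
                            spike_train(1, t1 + sh, t_end = 60))
  expect_equal(d_orig, d_shift, tolerance = 0.02)
})

test_that("grid refinement and the dense-grid reference agree", {
  set.seed(4)
  for (rep in 1:10) {
    a <- poisson_times(runif(1, 2, 10), 60)
    b <- poisson_times(runif(1, 2, 10), 60)
    sa <- spike_train(0, a, t_end = 60); sb <- spike_train(1, b, t_end = 60)
    d1 <- spike_distance(sa, sb, 1e-3)
    expect_lt(abs(d1 - spike_distance(sa, sb, 1e-4)), 2e-3)
    expect_lt(abs(d1 - ref_spike_distance(a, b, 60, 1e-4)), 1e-3)
  }
})

test_that("raw synchrony is one minus the distance", {
  set.seed(5)
  a <- poisson_train(5, 60); b <- poisson_train(8, 60, 1)
  expect_equal(raw_synchrony(a, b), 1 - spike_distance(a, b))
})

test_that("empty trains are rejected with a pointer to the activity filter", {
  a <- poisson_train(5, 60)
  e <- spike_train(1, numeric(), t_end = 60)
  expect_error(spike_distance(a, e), "filter_active_electrodes")
})

test_that("normalized synchrony is near zero under rate-matched independence", {
  set.seed(6)
  vals <- replicate(30, {
    a <- poisson_train(5, 60); b <- poisson_train(5, 60, 1)
    normalized_synchrony(a, b, synchrony_params(seed = 99))
  })
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("planted common burst structure scores high synchrony", {
  set.seed(7)
  ev <- sort(runif(30, 1, 119))
  sizes <- sample(6:15, 30, replace = TRUE)
  mk <- function(id) {
    t <- unlist(mapply(function(t0, n) t0 + rnorm(1, 0, 0.002) +
                         (seq_len(n) - 1) * 0.03, ev, sizes))
    spike_train(id, unique(sort(t[t >= 0 & t < 120])), t_end = 120)
  }
  expect_gt(normalized_synchrony(mk(0), mk(1)), 0.8)
})

test_that("normalized synchrony of independent pairs is density-invariant", {
  set.seed(8)
  sync_at <- function(rate) mean(replicate(12, {
    a <- poisson_train(rate, 60); b <- poisson_train(rate, 60, 1)
    normalized_synchrony(a, b, synchrony_params(seed = 5))
  }))
  expect_lt(abs(sync_at(1) - sync_at(20)), 0.1)
})

test_that("pairwise matrix is symmetric, unit-diagonal and seeded", {
  dur <- 30
  tm <- sort(runif(120, 0, dur))
  rec <- recording(list(spike_train(0, tm, t_end = dur),
                        spike_train(1, tm, t_end = dur)), duration = dur)
  m <- pairwise_matrix(rec)
  expect_equal(unname(m$values), matrix(1, 2, 2))

  set.seed(9)
  rec3 <- recording(lapply(0:2, function(i)
    poisson_train(6, dur, i)), duration = dur)
  m3 <- pairwise_matrix(rec3, synchrony_params(seed = 3))
  expect_equal(m3$values, t(m3$values))
  expect_equal(unname(diag(m3$values)), rep(1, 3))
  expect_true(all(m3$values >= 0 & m3$values <= 1))
  expect_length(unique(upper_links <- m3$values[upper.tri(m3$values)]), 3)
  # deterministic under the same seed
  m3b <- pairwise_matrix(rec3, synchrony_params(seed = 3))
  expect_identical(m3$values, m3b$values)

  expect_warning(m1 <- pairwise_matrix(
    recording(list(poisson_train(6, dur)), duration = dur)), "fewer than 2")
  expect_equal(dim(m1$values), c(1L, 1L))
})

test_that("planted communities separate within from between synchrony", {
  m <- network_model(n_electrodes = 12)
  rec <- generate_recording(m, duration = 180, seed = 31)
  act <- filter_active_electrodes(rec)
  sm <- pairwise_matrix(act, synchrony_params(seed = 1))
  ids <- electrode_ids(act) + 1
  comm <- m$communities[ids]
  e <- synchrony_edges(sm)
  same <- comm[match(e$elec_i + 1, ids)] == comm[match(e$elec_j + 1, ids)]
  expect_gt(mean(e$synchrony[same]), mean(e$synchrony[!same]) + 0.2)
})

test_that("edge list matches the matrix upper triangle", {
  set.seed(10)
  rec <- recording(lapply(0:3, function(i) poisson_train(8, 20, i)),
                   duration = 20)
  m <- pairwise_matrix(rec, synchrony_params(n_surrogates = 2, seed = 1))
  e <- synchrony_edges(m)
  expect_equal(nrow(e), 6L)
  expect_equal(e$synchrony, m$values[upper.tri(m$values)])
  expect_true(all(e$elec_i < e$elec_j))
})
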