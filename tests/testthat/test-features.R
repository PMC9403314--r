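test_that("feature definitions hold on constructed trains", {
  # 60 evenly spread spikes in 60 s, no bursts
  st <- spike_train(0, seq(0.5, 59.5, length.out = 60), t_end = 60)
  f <- electrode_features(st, detect_bursts(st), 60)
  expect_equal(f$firing_rate, 1.0)
  expect_equal(f$n_bursts, 0L)
  expect_equal(f$pct_spikes_in_bursts, 0)
  expect_equal(f$mean_isi, mean(diff(st$times)))
  expect_true(is.na(f$mean_burst_duration))

  # a single 6-spike burst train over 60 s
  stb <- spike_train(0, seq(0, 0.25, by = 0.05), t_end = 60)
  fb <- electrode_features(stb, detect_bursts(stb), 60)
  expect_equal(fb$pct_spikes_in_bursts, 100)
  expect_equal(fb$bursts_per_min, 1.0)
  expect_equal(fb$mean_burst_duration, 0.25)

  # empty train: zero counts and rates, undefined means stay NA
  fe <- electrode_features(spike_train(0, numeric(), t_end = 60))
  expect_equal(fe$n_spikes, 0L)
  expect_equal(fe$firing_rate, 0)
  expect_true(is.na(fe$mean_isi))
  expect_true(is.na(fe$pct_spikes_in_bursts))

  expect_error(electrode_features(st, detect_bursts(st), 0), "positive")
})

test_that("weighted summary matches its definition and a brute-force loop", {
  s <- weighted_summary(c(2, 4), c(1, 3))
  expect_equal(s$mean, 3.5)
  # equal weights reduce to the unweighted population form
  x <- c(1, 5, 2, 8)
  s <- weighted_summary(x, rep(2, 4))
  expect_equal(s$mean, mean(x))
  expect_equal(s$sd, sqrt(mean((x - mean(x))^2)))
  # brute force on a random 50-electrode table
  set.seed(8)
  v <- rnorm(50); w <- runif(50)
  s <- weighted_summary(v, w)
  m_loop <- 0; W <- 0
  for (i in 1:50) { m_loop <- m_loop + w[i] * v[i]; W <- W + w[i] }
  m_loop <- m_loop / W
  v_loop <- 0
  for (i in 1:50) v_loop <- v_loop + w[i] * (v[i] - m_loop)^2
  expect_equal(s$mean, m_loop, tolerance = 1e-12)
  expect_equal(s$sd, sqrt(v_loop / W), tolerance = 1e-12)
  # single electrode: (value, 0); NA values drop with their weights
  expect_equal(weighted_summary(7, 3)[c("mean", "sd")], list(mean = 7, sd = 0))
  expect_equal(weighted_summary(c(7, NA), c(3, 100))$mean, 7)
  expect_warning(s0 <- weighted_summary(c(NA_real_, NA_real_), c(1, 1)))
  expect_true(is.na(s0$mean))
  expect_warning(weighted_summary(c(1, 2), c(0, 0)))
})

test_that("fold change is the ratio to baseline with guarded degenerate cases", {
  base <- data.frame(feature = c("firing_rate", "n_bursts"),
                     weighted_mean = c(10, 0), weighted_sd = 0,
                     n_active_electrodes = 5)
  tp <- transform(base, weighted_mean = c(5, 3))
  expect_warning(fc <- fold_change(tp, base), "baseline")
  expect_equal(fc$fold_change[fc$feature == "firing_rate"], 0.5)
  expect_true(is.na(fc$fold_change[fc$feature == "n_bursts"]))
  # a summary against itself is 1 everywhere defined
  rec <- generate_recording(network_model(n_electrodes = 10), duration = 60,
                            seed = 2)
  s <- well_summary(filter_active_electrodes(rec))
  fc <- fold_change(s, s)
  expect_true(all(fc$fold_change[!is.na(fc$fold_change)] == 1))
})

test_that("count fold changes are scale-equivariant", {
  set.seed(15)
  mk <- function(scale) {
    trains <- lapply(1:8, function(i) {
      n <- round(scale * (20 + 5 * i))
      spike_train(i - 1L, sort(runif(n, 0, 60)), t_end = 60)
    })
    recording(trains, duration = 60)
  }
  s1 <- well_summary(mk(1), weighting = "uniform")
  s3 <- well_summary(mk(3), weighting = "uniform")
  # the Poisson trains have no bursts, so burst-feature baselines warn
  fc <- suppressWarnings(fold_change(s3, s1))
  got <- fc$fold_change[fc$feature == "n_spikes"]
  expect_equal(got, 3, tolerance = 0.02)
})

test_that("Poisson trains recover their rate and mean ISI at long duration", {
  set.seed(23)
  st <- poisson_train(5, 1800)
  f <- electrode_features(st, detect_bursts(st), 1800)
  expect_equal(f$firing_rate, 5, tolerance = 0.05)
  expect_equal(f$mean_isi, 1 / 5, tolerance = 0.05)
})

test_that("study fold-change table is tidy, baseline-anchored and validated", {
  m <- network_model(n_electrodes = 12)
  recs <- list(
    generate_recording(m, 120, 1.0, seed = 1, well_id = "w1", timepoint = "baseline"),
    generate_recording(m, 120, 0.4, seed = 2, well_id = "w1", timepoint = "24h"),
    generate_recording(m, 120, 1.0, seed = 3, well_id = "w2", timepoint = "baseline"),
    generate_recording(m, 120, 1.0, seed = 4, well_id = "w2", timepoint = "24h"))
  tab <- fold_change_table(recs)
  expect_setequal(unique(tab$well), c("w1", "w2"))
  base_fc <- tab$fold_change[tab$timepoint == "baseline" & !is.na(tab$fold_change)]
  expect_true(all(base_fc == 1))
  fc_w1 <- tab$fold_change[tab$well == "w1" & tab$timepoint == "24h" &
                           tab$feature == "n_spikes"]
  expect_lt(fc_w1, 0.7)
  # every well needs a baseline
  expect_error(fold_change_table(recs[c(2, 3)]), "w1")
})
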