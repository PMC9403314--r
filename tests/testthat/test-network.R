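mat_from <- function(A, ids = seq_len(nrow(A)) - 1L) {
  diag(A) <- 1
  dimnames(A) <- list(paste0("e", ids), paste0("e", ids))
  structure(list(electrode_ids = as.integer(ids), values = A),
            class = "synchrony_matrix")
}

test_that("Louvain recovers two planted blocks exactly", {
  A <- matrix(0.05, 10, 10)
  A[1:5, 1:5] <- 0.9
  A[6:10, 6:10] <- 0.9
  part <- louvain_partition(mat_from(A), seed = 0)
  expect_equal(part$n_communities, 2L)
  expect_length(unique(part$membership[1:5]), 1)
  expect_length(unique(part$membership[6:10]), 1)
  expect_false(part$membership[1] == part$membership[6])
  # reported Q equals the package's weighted-modularity formula and igraph's
  g <- synchrony_graph(mat_from(A))
  expect_equal(part$modularity,
               modularity_weighted(g, part$membership))
  expect_equal(part$modularity,
               igraph::modularity(g, part$membership,
                                  weights = igraph::E(g)$weight))
})

test_that("degenerate graphs are handled", {
  single <- mat_from(matrix(1, 1, 1))
  part <- louvain_partition(single)
  expect_equal(part$n_communities, 1L)
  expect_equal(part$modularity, 0)
  expect_error(louvain_partition(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("Louvain modularity is bounded by the exhaustive optimum on small graphs", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(5:7, 1)
    A <- matrix(runif(n * n), n, n)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 0
    best <- ref_best_modularity(A)
    part <- louvain_partition(mat_from(A), seed = rep)
    expect_lte(part$modularity, best + 1e-9)
  }
  # and attains it on a well-separated planted case
  A <- matrix(0.05, 8, 8)
  A[1:4, 1:4] <- 0.9; A[5:8, 5:8] <- 0.9
  diag(A) <- 0
  part <- louvain_partition(mat_from(A), seed = 0)
  expect_equal(part$modularity, ref_best_modularity(A), tolerance = 1e-9)
})

test_that("returned partition beats the all-singletons baseline", {
  set.seed(13)
  A <- matrix(runif(64, 0.1, 0.9), 8, 8)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  m <- mat_from(A)
  g <- synchrony_graph(m)
  part <- louvain_partition(m, seed = 1)
  expect_gte(part$modularity,
             modularity_weighted(g, seq_len(8)))
})

test_that("partitions are stable under node relabeling", {
  set.seed(14)
  pm <- planted_matrix(12)
  part <- louvain_partition(mat_from(pm$A), seed = 0)
  perm <- sample(12)
  part_p <- louvain_partition(mat_from(pm$A[perm, perm]), seed = 0)
  # mapped back, the grouping is identical up to community ids
  back <- integer(12); back[perm] <- part_p$membership
  expect_equal(mclust::adjustedRandIndex(part$membership, back), 1)
})

test_that("links are classified strictly above the strong threshold", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.69
  A[1, 3] <- A[3, 1] <- 0.70
  A[2, 3] <- A[3, 2] <- 0.71
  cl <- classify_links(mat_from(A))
  expect_equal(as.character(cl$strength[order(cl$synchrony)]),
               c("weak", "weak", "strong"))
  # all-1 matrix: everything strong; threshold 0: every positive link strong
  all1 <- mat_from(matrix(1, 3, 3))
  expect_true(all(classify_links(all1)$strength == "strong"))
  expect_true(all(classify_links(mat_from(A), 0)$strength == "strong"))
})

test_that("synchrony distribution finds the two planted modes", {
  set.seed(15)
  vals <- c(pmin(pmax(rnorm(400, 0.4, 0.05), 0), 1),
            pmin(pmax(rnorm(400, 0.95, 0.03), 0), 1))
  d <- synchrony_distribution(vals)
  expect_gte(length(d$peaks), 2)
  expect_true(any(d$peaks >= 0.3 & d$peaks <= 0.5))
  expect_true(any(d$peaks >= 0.9 & d$peaks <= 1.0))
  expect_equal(d$mean, mean(vals))
  expect_equal(sum(d$histogram$density * diff(d$histogram$bin_left[1:2])), 1,
               tolerance = 1e-9)
  # degenerate and empty inputs
  d1 <- synchrony_distribution(rep(0.5, 10))
  expect_equal(d1$peaks, 0.5)
  expect_warning(d0 <- synchrony_distribution(numeric()), "no synchrony")
  expect_true(is.na(d0$mean))
})

test_that("device-level synchrony averages the links", {
  A <- matrix(0, 3, 3)
  A[upper.tri(A)] <- c(0.2, 0.4, 0.9)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  expect_equal(device_average_synchrony(mat_from(A)), 0.5)
  set.seed(16)
  B <- matrix(runif(36), 6, 6); B[lower.tri(B)] <- t(B)[lower.tri(B)]
  m <- mat_from(B)
  acc <- 0; n <- 0
  for (i in 1:5) for (j in (i + 1):6) { acc <- acc + m$values[i, j]; n <- n + 1 }
  expect_equal(device_average_synchrony(m), acc / n)
  expect_warning(out <- device_average_synchrony(mat_from(matrix(1, 1, 1))))
  expect_true(is.na(out))
})

test_that("identical electrodes give unit device synchrony end to end", {
  tm <- sort(runif(80, 0, 30))
  rec <- recording(lapply(0:2, function(i) spike_train(i, tm, t_end = 30)),
                   duration = 30)
  m <- pairwise_matrix(rec)
  expect_equal(device_average_synchrony(m), 1)
})
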