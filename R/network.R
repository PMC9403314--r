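#' Complete weighted graph from a synchrony matrix
#'
#' Nodes are the active electrodes; every unordered pair carries its
#' normalised synchrony as edge weight (a "link"). No thresholding is
#' applied here: the strong/weak cutoff is a display classification, see
#' [classify_links()].
#'
#' @param m A `synchrony_matrix` from [pairwise_matrix()].
#' @return An [igraph::graph] with vertex attribute `electrode` and edge
#'   attribute `weight`.
#' @export
synchrony_graph <- function(m) {
  stopifnot(inherits(m, "synchrony_matrix"))
  g <- igraph::graph_from_adjacency_matrix(m$values, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$electrode <- m$electrode_ids
  g
}

#' Louvain community detection on the synchrony graph
#'
#' Greedy two-phase modularity maximisation (local moves, then aggregation,
#' iterated) on the complete weighted synchrony graph. The node visit order
#' is randomised, so a seed fixes the result. The reported `modularity` is
#' re-evaluated on the returned partition with the weighted-modularity
#' formula (fraction of within-community weight minus its expectation under
#' the degree-preserving null).
#'
#' @param g Graph from [synchrony_graph()] (or a `synchrony_matrix`, which
#'   is converted).
#' @param seed Integer seed (default 0).
#' @param resolution Resolution parameter of the modularity objective
#'   (default 1).
#' @return A list of class `community_partition`: `membership` (named
#'   integer vector, community ids 1..k), `modularity`, `n_communities`.
#' @export
louvain_partition <- function(g, seed = 0, resolution = 1) {
  if (inherits(g, "synchrony_matrix")) g <- synchrony_graph(g)
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0) stop("empty graph")
  cl <- with_seed(seed,
                  igraph::cluster_louvain(g, resolution = resolution))
  mem <- igraph::membership(cl)
  structure(list(membership = mem,
                 modularity = modularity_weighted(g, mem),
                 n_communities = length(unique(mem))),
            class = "community_partition")
}

#' Weighted modularity of a partition
#'
#' `Q = sum_c (w_c / W - (s_c / 2W)^2)` where `w_c` is the total
#' within-community edge weight, `s_c` the total strength of the community's
#' nodes and `W` the total edge weight. Written out directly so it can
#' cross-check community detection output.
#'
#' @param g Weighted undirected igraph.
#' @param membership Community id per vertex.
#' @return Scalar Q in `[-0.5, 1]`; 0 for a graph with no edges.
#' @export
modularity_weighted <- function(g, membership) {
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  W <- sum(w)
  if (W == 0) return(0)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  same <- membership[ends[, 1]] == membership[ends[, 2]]
  strength <- igraph::strength(g)
  q <- 0
  for (c in unique(membership)) {
    wc <- sum(w[same & membership[ends[, 1]] == c])
    sc <- sum(strength[membership == c])
    q <- q + wc / W - (sc / (2 * W))^2
  }
  q
}

#' Classify links as strong or weak
#'
#' Strong means synchrony strictly above the threshold (default 0.7, the
#' cutoff drawn as a thick line in connectivity maps); ties at the threshold
#' are weak.
#'
#' @param m A `synchrony_matrix`.
#' @param strong_threshold Numeric cutoff in `[0, 1]`.
#' @return The [synchrony_edges()] table with an extra factor column
#'   `strength` (`"strong"`/`"weak"`).
#' @export
classify_links <- function(m, strong_threshold = 0.7) {
  edges <- synchrony_edges(m)
  edges$strength <- factor(ifelse(edges$synchrony > strong_threshold,
                                  "strong", "weak"),
                           levels = c("strong", "weak"))
  edges
}

#' Distribution summary of pooled link synchronies
#'
#' Histogram over `[0, 1]`, pooled mean, and density peaks (modes) from a
#' Gaussian kernel density estimate with Silverman's bandwidth. A peak is a
#' local maximum of the density with prominence at least `min_prominence`
#' times the maximum density; two or more peaks indicate bimodality.
#'
#' @param values Link synchronies in `[0, 1]` (pooled across wells).
#' @param n_bins Number of histogram bins (default 25).
#' @param min_prominence Minimum relative prominence of a reported peak.
#' @return List: `histogram` (data.frame `bin_left`, `bin_right`,
#'   `density`), `mean`, `peaks` (numeric vector of mode locations,
#'   ascending). Empty input yields empty components with a warning.
#' @export
synchrony_distribution <- function(values, n_bins = 25,
                                   min_prominence = 0.1) {
  values <- values[!is.na(values)]
  if (!length(values)) {
    warning("no synchrony values to summarise")
    return(list(histogram = data.frame(bin_left = numeric(),
                                       bin_right = numeric(),
                                       density = numeric()),
                mean = NA_real_, peaks = numeric()))
  }
  stopifnot(all(values >= 0 & values <= 1))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  hist_df <- data.frame(bin_left = utils::head(breaks, -1),
                        bin_right = breaks[-1], density = h$density)
  peaks <- if (stats::sd(values) == 0) unique(values)
           else density_peaks(values, min_prominence)
  list(histogram = hist_df, mean = mean(values), peaks = peaks)
}

density_peaks <- function(values, min_prominence = 0.1) {
  d <- stats::density(values, bw = "nrd0", from = 0, to = 1, n = 512)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(is_max)) return(d$x[which.max(y)])
  # prominence: height above the higher of the valleys separating the peak
  # from its neighbouring peaks (or the domain edges)
  bounds <- c(1L, is_max, length(y))
  prom <- vapply(seq_along(is_max), function(k) {
    i <- is_max[k]
    left <- min(y[bounds[k]:i])
    right <- min(y[i:bounds[k + 2L]])
    y[i] - max(left, right)
  }, numeric(1))
  keep <- prom >= min_prominence * max(y)
  if (!any(keep)) keep <- which.max(prom)
  sort(d$x[is_max[keep]])
}

#' Device-level average synchrony
#'
#' Arithmetic mean over all links (upper-triangle values) of a well's
#' synchrony matrix — the per-well summary compared across conditions and
#' timepoints.
#'
#' @param m A `synchrony_matrix`.
#' @return Scalar mean synchrony; `NA` with a warning when there are no
#'   links.
#' @export
device_average_synchrony <- function(m) {
  vals <- upper_links(m)
  if (!length(vals)) {
    warning("no links: average synchrony undefined")
    return(NA_real_)
  }
  mean(vals)
}
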