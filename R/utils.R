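#' @useDynLib meanet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Deterministic stream of child seeds from a master seed and a stream id.
# Keeps everything in 31-bit signed integer range. A simple multiplicative
# hash is enough here: children only need to be distinct and reproducible.
derive_seeds <- function(master, stream, n = 1L) {
  master <- as.double(master %% 2147483647)
  stream <- as.double(stream %% 2147483647)
  x <- (master * 2654435761 + stream * 40503 + 12345) %% 2147483647
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (x * 48271) %% 2147483647
    out[i] <- x
  }
  as.integer(out)
}

# restore the caller's RNG state on exit
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}
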