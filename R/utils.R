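#' @keywords internal
"_PACKAGE"

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 16807) %% 2147483647
}

#' Agreement between two partitions up to label permutation
#'
#' Fraction of elements on which two labelings agree after optimally matching
#' the labels of one to the other. For label sets of size up to 8 the matching
#' is exact (all permutations searched); beyond that a greedy majority
#' matching on the confusion matrix is used.
#'
#' @param a,b integer or factor label vectors of equal length.
#' @return Fraction in \[0, 1\] of elements assigned consistently.
#' @export
partition_agreement <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  a <- as.integer(factor(a))
  b <- as.integer(factor(b))
  ka <- max(a); kb <- max(b)
  if (ka > kb) { tmp <- a; a <- b; b <- tmp; tmp <- ka; ka <- kb; kb <- tmp }
  conf <- table(factor(a, levels = seq_len(ka)), factor(b, levels = seq_len(kb)))
  if (kb <= 8L) {
    perms <- permutations_of(seq_len(kb))
    best <- 0L
    for (p in perms) {
      hit <- sum(conf[cbind(seq_len(ka), p[seq_len(ka)])])
      if (hit > best) best <- hit
    }
    return(best / length(a))
  }
  # greedy: repeatedly take the largest confusion cell with unused row/column
  conf <- as.matrix(conf)
  hit <- 0L
  for (k in seq_len(ka)) {
    idx <- arrayInd(which.max(conf), dim(conf))
    hit <- hit + conf[idx]
    conf[idx[1], ] <- -1L
    conf[, idx[2]] <- -1L
  }
  hit / length(a)
}

# All permutations of a vector (used for exact label matching, n <= 8).
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_of(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}

# Canonical relabeling: communities numbered by first appearance.
canonicalize_labels <- function(labels) {
  match(labels, unique(labels))
}
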