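# Independent oracles and fixture builders for the test suite.

# All set partitions of n elements as restricted-growth label rows.
set_partitions <- function(n) {
  rows <- list(c(1L))
  for (el in seq_len(n - 1L)) {
    rows <- unlist(lapply(rows, function(r) {
      k <- max(r)
      lapply(seq_len(k + 1L), function(lab) c(r, lab))
    }), recursive = FALSE)
  }
  do.call(rbind, rows)
}

# Build a sparse_msn carrying every edge of a dense symmetric signed matrix
# (fixture for the multilayer machinery; bypasses thresholding on purpose).
full_msn <- function(A, regions = NULL) {
  N <- nrow(A)
  if (is.null(regions)) regions <- sprintf("n%02d", seq_len(N))
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      region_i = regions[idx[, 1]], region_j = regions[idx[, 2]],
                      weight = A[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$i, edges$j), ]
  rownames(edges) <- NULL
  structure(list(edges = edges, edge_count = nrow(edges),
                 density_pct = 100 * nrow(edges) / (N * (N - 1) / 2),
                 N = N, regions = regions, subject = NA_character_,
                 feature_set = NA_character_, atlas_name = NA_character_),
            class = "sparse_msn")
}

# Random signed symmetric matrix with distinct |weights|, zero diagonal.
random_sym_matrix <- function(N, seed) {
  set.seed(seed)
  A <- matrix(0, N, N)
  w <- stats::rnorm(N * (N - 1) / 2)
  A[upper.tri(A)] <- w
  A + t(A)
}

# Random small multilayer stack built through the package surface.
random_small_stack <- function(N, L, seed, omega = NULL, gamma = 1) {
  set.seed(seed)
  if (is.null(omega)) omega <- stats::runif(1, 0, 2)
  layers <- lapply(seq_len(L), function(s)
    full_msn(random_sym_matrix(N, seed * 1000L + s)))
  multilayer_stack(layers, gamma = gamma, omega = omega, ordering = "as-is")
}

# Direct multislice quality of one labels matrix, written straight from the
# quality definition (signed per-layer null models, ordinal coupling, 1/2mu).
# Shares nothing with the package's build_supra/evaluate_Qml code paths.
oracle_Qml <- function(layers, gamma, omega, labels_matrix) {
  L <- length(layers)
  N <- nrow(layers[[1]])
  gamma <- rep_len(gamma, L)
  total <- 0
  two_mu <- 2 * omega * N * (L - 1)
  for (s in seq_len(L)) {
    A <- layers[[s]]
    two_mu <- two_mu + sum(abs(A))
    g <- labels_matrix[, s]
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (g[i] != g[j]) next
      a <- A[i, j]
      p <- 0
      twom_p <- sum(A[A > 0])
      if (twom_p > 0)
        p <- p + sum(A[i, ][A[i, ] > 0]) * sum(A[j, ][A[j, ] > 0]) / twom_p
      twom_n <- sum(-A[A < 0])
      if (twom_n > 0)
        p <- p - sum(-A[i, ][A[i, ] < 0]) * sum(-A[j, ][A[j, ] < 0]) / twom_n
      total <- total + max(a, 0) - max(-a, 0) - gamma[s] * p
    }
  }
  for (s in seq_len(L - 1L))
    total <- total + 2 * omega *
      sum(labels_matrix[, s] == labels_matrix[, s + 1L])
  total / two_mu
}

# Exhaustive maximum of the multislice quality over every partition of the
# (node, layer) units. Vectorized over partitions for tractable sizes
# (N * L <= 10 in the suites).
oracle_best_Qml <- function(stack) {
  N <- stack$N; L <- stack$L
  n <- N * L
  parts <- set_partitions(n)
  # contribution weight of every supra unit pair, from the quality definition
  W <- matrix(0, n, n)
  gamma <- rep_len(stack$gamma, L)
  for (s in seq_len(L)) {
    A <- stack$layers[[s]]
    Ap <- pmax(A, 0); An <- pmax(-A, 0)
    P <- matrix(0, N, N)
    if (sum(Ap) > 0) P <- P + outer(rowSums(Ap), rowSums(Ap)) / sum(Ap)
    if (sum(An) > 0) P <- P - outer(rowSums(An), rowSums(An)) / sum(An)
    rows <- (s - 1L) * N + seq_len(N)
    W[rows, rows] <- A - gamma[s] * P
    if (s < L) {
      W[cbind(rows, rows + N)] <- stack$omega
      W[cbind(rows + N, rows)] <- stack$omega
    }
  }
  two_mu <- sum(vapply(stack$layers, function(A) sum(abs(A)), 0)) +
    2 * stack$omega * N * (L - 1)
  q <- numeric(nrow(parts))
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (W[u, v] == 0) next
    q <- q + W[u, v] * (parts[, u] == parts[, v])
  }
  q <- q / two_mu
  best <- which.max(q)
  list(Q = q[best],
       labels_matrix = matrix(parts[best, ], N, L),
       n_partitions = nrow(parts))
}

# Exhaustive single-layer signed modularity maximum (per-sign normalization).
oracle_best_single_Q <- function(A, gamma = 1) {
  n <- nrow(A)
  parts <- set_partitions(n)
  best <- -Inf; best_labels <- NULL
  for (r in seq_len(nrow(parts))) {
    q <- single_layer_Q(A, parts[r, ], gamma)
    if (q > best) { best <- q; best_labels <- parts[r, ] }
  }
  list(Q = best, labels = best_labels)
}

# Small synthetic cohort shared by several suites.
make_test_cohort <- function(n_subjects = 8, atlas = generate_atlas("DKA"),
                             seed = 42, effect = 0.9, noise_sd = 0.2) {
  generate_cohort(n_subjects = n_subjects, atlas = atlas, seed = seed,
                  effect = effect, noise_sd = noise_sd)
}
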