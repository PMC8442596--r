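# Shared fixtures: small graphs and cohorts built in code at test time.

# adjacency from an edge list on n nodes
adj_from_edges <- function(n, edges, density = NA_real_) {
  A <- matrix(0, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  if (is.na(density)) density <- sum(A) / (n * (n - 1))
  adjacency(A, density = density)
}

complete_adj <- function(n) {
  A <- matrix(1, n, n) - diag(n)
  adjacency(A, density = 1)
}

star_adj <- function(k) {
  # node 1 is the centre, nodes 2..k+1 the leaves
  n <- k + 1L
  A <- matrix(0, n, n)
  A[1, 2:n] <- 1
  A[2:n, 1] <- 1
  adjacency(A, density = k / (n * (n - 1) / 2))
}

# Erdos-Renyi adjacency, guaranteed at least one edge
random_adj <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  repeat {
    U <- matrix(0, n, n)
    U[upper.tri(U)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
    A <- U + t(U)
    if (sum(A) > 0) return(adjacency(A, density = sum(A) / (n * (n - 1))))
  }
}

# independent power-iteration oracle for eigenvector centrality
power_iteration_ec <- function(A, tol = 1e-14, max_iter = 10000) {
  M <- if (inherits(A, "adjacency")) A$values else A
  v <- rep(1, nrow(M)) / sqrt(nrow(M))
  for (i in seq_len(max_iter)) {
    w <- M %*% v
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) break
    v <- w
  }
  as.numeric(w)
}

# brute-force participation coefficient: explicit loop over nodes and
# communities
brute_pc <- function(A, labels) {
  M <- if (inherits(A, "adjacency")) A$values else A
  n <- nrow(M)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ki <- sum(M[i, ])
    if (ki == 0) { out[i] <- 0; next }
    s <- 0
    for (m in unique(labels)) {
      kim <- sum(M[i, labels == m])
      s <- s + (kim / ki)^2
    }
    out[i] <- 1 - s
  }
  out
}

# small stationary cohort for fast pipeline-level tests
quick_ts <- function(n_parcels = 20, T = 200, seed = 1) {
  sizes <- rep(n_parcels %/% 4, 4)
  sizes[1] <- sizes[1] + n_parcels - sum(sizes)
  spec <- cohort_spec(n_participants = 1, n_parcels = n_parcels,
                      community_sizes = sizes,
                      n_timepoints = T, seed = seed)
  generate_modular_timeseries(spec, 1)$ts
}
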