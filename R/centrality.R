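#' Eigenvector centrality of a binary undirected network
#'
#' The leading eigenvector of the adjacency matrix, sign-fixed to be
#' non-negative and scaled to unit Euclidean norm, so that
#' `EC = (1/lambda1) A EC` componentwise. Computed by symmetric
#' eigendecomposition for determinism. On disconnected graphs the vector of
#' the globally largest eigenvalue is returned: its support concentrates on
#' one component and other components receive near-zero centrality.
#'
#' @param A an `adjacency` (or plain binary symmetric matrix).
#' @return A `centrality_vector` of kind `"EC"` with attribute `eigenvalue`.
#' @export
eigenvector_centrality <- function(A) {
  M <- adj_values(A)
  if (sum(M) == 0) stop("eigenvector centrality undefined on an edgeless graph")
  e <- eigen(M, symmetric = TRUE)
  lambda1 <- e$values[1]
  v <- e$vectors[, 1]
  # fix sign: Perron vector of the leading eigenvalue is non-negative up to
  # a global sign
  if (sum(v) < 0) v <- -v
  v[v < 0 & v > -1e-12] <- 0
  v <- v / sqrt(sum(v^2))
  centrality_vector(v, kind = "EC", parcel_ids = rownames(M),
                    eigenvalue = lambda1)
}

#' Louvain community detection with seeded restarts
#'
#' Greedy two-phase modularity maximization (Newman-Girvan modularity at
#' resolution `gamma`). The node sweep order is randomized per restart from
#' the seed; the best-modularity partition over `n_restarts` runs is
#' returned. Community labels are relabelled to contiguous integers in order
#' of first appearance.
#'
#' @param A an `adjacency` or binary symmetric matrix.
#' @param gamma resolution parameter (1 = classic modularity).
#' @param seed integer seed controlling restarts.
#' @param n_restarts number of seeded runs; the best Q wins.
#' @return A list of class `partition` with `labels`, `modularity`, `gamma`,
#'   `seed`.
#' @export
louvain_partition <- function(A, gamma = 1, seed = 1L, n_restarts = 100L) {
  M <- adj_values(A)
  g <- igraph::graph_from_adjacency_matrix(M, mode = "undirected")
  best_q <- -Inf
  best <- NULL
  for (k in seq_len(n_restarts)) {
    set.seed(as.integer((seed + k - 1L) %% .Machine$integer.max))
    cl <- igraph::cluster_louvain(g, resolution = gamma)
    q <- max(cl$modularity)
    if (q > best_q) {
      best_q <- q
      best <- igraph::membership(cl)
    }
  }
  labels <- as.integer(factor(best, levels = unique(as.integer(best))))
  structure(list(labels = labels, modularity = best_q, gamma = gamma,
                 seed = seed),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes, %d communities, Q = %.4f (gamma %g)\n",
              length(x$labels), max(x$labels), x$modularity, x$gamma))
  invisible(x)
}

#' Participation coefficient
#'
#' `PC_i = 1 - sum_m (K_i(m)/K_i)^2`, where `K_i` is the degree of node i
#' and `K_i(m)` the number of its edges into community m. High PC marks
#' connector hubs whose edges spread across modules. Isolated nodes get 0
#' by convention.
#'
#' @param A an `adjacency` or binary symmetric matrix.
#' @param P a `partition` labelling every node of A.
#' @return A `centrality_vector` of kind `"PC"` with attribute `degrees`.
#' @export
participation_coefficient <- function(A, P) {
  M <- adj_values(A)
  labels <- if (inherits(P, "partition")) P$labels else as.integer(P)
  n <- nrow(M)
  if (length(labels) != n) {
    stop("partition labels (", length(labels),
         ") do not match node count (", n, ")")
  }
  deg <- rowSums(M)
  # K_i(m): cross-tabulate edges by the community of the opposite endpoint
  comm <- sort(unique(labels))
  Km <- vapply(comm, function(m) rowSums(M[, labels == m, drop = FALSE]),
               numeric(n))
  pc <- 1 - rowSums((Km / pmax(deg, 1))^2)
  pc[deg == 0] <- 0
  centrality_vector(pc, kind = "PC", parcel_ids = rownames(M), degrees = deg)
}

#' Flow coefficient
#'
#' Local centrality of a node in a binary undirected graph: the fraction of
#' ordered pairs of distinct neighbors (a, b) that are not directly linked
#' a-b, i.e. pairs whose shortest connection passes through the node. For a
#' node of degree k >= 2 this equals 1 minus its local clustering
#' coefficient; nodes with degree < 2 get 0.
#'
#' @param A an `adjacency` or binary symmetric matrix.
#' @return A `centrality_vector` of kind `"flow"` with values in `[0, 1]`.
#' @export
flow_coefficient <- function(A) {
  M <- adj_values(A)
  deg <- rowSums(M)
  # closed neighbor triangles: diag(A^3) counts 2x ordered connected pairs
  tri2 <- diag(M %*% M %*% M)  # = 2 * triangles through i (ordered pairs linked)
  denom <- deg * (deg - 1)
  f <- ifelse(deg >= 2, (denom - tri2) / denom, 0)
  centrality_vector(f, kind = "flow", parcel_ids = rownames(M))
}

# Accept an adjacency object or plain matrix, validating the latter.
adj_values <- function(A) {
  if (inherits(A, "adjacency")) return(A$values)
  M <- as.matrix(A)
  if (nrow(M) != ncol(M)) stop("adjacency matrix must be square")
  if (!all(M %in% c(0, 1))) stop("adjacency entries must be 0/1")
  if (any(diag(M) != 0)) stop("adjacency diagonal must be zero")
  if (!isTRUE(all.equal(M, t(M), check.attributes = FALSE))) {
    stop("adjacency must be symmetric")
  }
  M
}
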