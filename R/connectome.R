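#' Z-score runs and concatenate them along time
#'
#' Each parcel's signal is standardized to mean 0 and standard deviation 1
#' within each run independently; runs are then joined along the time axis
#' and the join points recorded as run boundaries.
#'
#' @param runs a single `parcel_ts` or a list of them sharing parcel IDs and
#'   TR.
#' @return A `parcel_ts` with standardized, concatenated values.
#' @export
standardize_and_concatenate <- function(runs) {
  if (inherits(runs, "parcel_ts")) runs <- list(runs)
  if (!length(runs) || !all(vapply(runs, inherits, logical(1), "parcel_ts"))) {
    stop("runs must be parcel_ts objects")
  }
  ids <- runs[[1]]$parcel_ids
  tr <- runs[[1]]$tr_seconds
  for (k in seq_along(runs)) {
    if (!identical(runs[[k]]$parcel_ids, ids)) {
      stop("run ", k, " has a different parcel set")
    }
    if (runs[[k]]$tr_seconds != tr) stop("run ", k, " has a different TR")
  }
  zs <- lapply(seq_along(runs), function(k) {
    v <- runs[[k]]$values
    mu <- rowMeans(v)
    sdv <- apply(v, 1, stats::sd)
    bad <- which(sdv == 0)
    if (length(bad)) {
      stop("zero-variance parcel '", ids[bad[1]], "' in run ", k)
    }
    (v - mu) / sdv
  })
  lens <- vapply(zs, ncol, integer(1))
  boundaries <- cumsum(c(1L, lens[-length(lens)]))
  parcel_ts(do.call(cbind, zs), parcel_ids = ids, tr_seconds = tr,
            run_boundaries = boundaries)
}

#' Pearson correlation matrix of a parcel time series
#'
#' @param ts a `parcel_ts` with at least 3 samples.
#' @return A `corr_matrix`.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (n_timepoints(ts) < 3L) stop("need at least 3 time points")
  sdv <- apply(ts$values, 1, stats::sd)
  if (any(sdv == 0)) {
    stop("zero-variance parcel '", ts$parcel_ids[which(sdv == 0)[1]], "'")
  }
  C <- stats::cor(t(ts$values))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  corr_matrix(C, parcel_ids = ts$parcel_ids)
}

# Edge count implied by a proportional density over unordered node pairs,
# with round-half-up so e.g. 0.5 -> 1.
edge_count_for_density <- function(density, n) {
  floor(density * n * (n - 1) / 2 + 0.5)
}

#' Proportional threshold: keep the strongest fraction of edges
#'
#' Retains the `round(density * N(N-1)/2)` largest off-diagonal correlations
#' (signed values, unordered pairs) and binarizes: retained pairs become
#' symmetric 1-edges, everything else 0, zero diagonal. Ties at the cutoff
#' value are broken by ascending (row, column) index, so the edge set is
#' deterministic and nested across densities.
#'
#' @param C a `corr_matrix` (or plain symmetric matrix).
#' @param density proportion of possible edges to retain, in `(0, 1]`.
#' @return An `adjacency`.
#' @export
proportional_threshold <- function(C, density) {
  if (inherits(C, "corr_matrix")) {
    ids <- C$parcel_ids
    M <- C$values
  } else {
    M <- as.matrix(C)
    ids <- rownames(M)
  }
  n <- nrow(M)
  if (n < 2L) stop("need at least 2 nodes")
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1) {
    stop("density must lie in (0, 1]")
  }
  m <- edge_count_for_density(density, n)
  ut <- which(upper.tri(M))
  # order by value descending; ties by linear index ascending (column-major
  # upper triangle == ascending (row, column))
  ord <- ut[order(-M[ut], ut)]
  keep <- ord[seq_len(min(m, length(ord)))]
  A <- matrix(0, n, n)
  A[keep] <- 1
  A <- A + t(A)
  adjacency(A, density = density, parcel_ids = ids)
}

#' Select the edge density maximizing the mean flow coefficient
#'
#' Thresholds the correlation matrix at each candidate density, computes the
#' mean flow coefficient across nodes, and returns the candidate with the
#' largest mean (first maximum on ties).
#'
#' @param C a `corr_matrix`.
#' @param candidates densities to evaluate; default
#'   `c(0.025, 0.05, 0.075, 0.10, 0.125, 0.15)`.
#' @return A list with `density` (selected candidate), `profile` (named
#'   numeric vector of mean flow coefficients per candidate).
#' @export
select_density_by_flow <- function(C,
    candidates = c(0.025, 0.05, 0.075, 0.10, 0.125, 0.15)) {
  if (!length(candidates)) stop("candidate list must not be empty")
  if (any(candidates <= 0 | candidates > 1)) {
    stop("candidates must lie in (0, 1]")
  }
  profile <- vapply(candidates, function(d) {
    A <- proportional_threshold(C, d)
    mean(flow_coefficient(A))
  }, numeric(1))
  names(profile) <- format(candidates)
  list(density = candidates[which.max(profile)], profile = profile)
}
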