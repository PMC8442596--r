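#' Parcel-by-time fMRI signal matrix
#'
#' Container for parcellated time series: one row per parcel (network node),
#' one column per sample (TR). Runs concatenated along time keep their join
#' points in `run_boundaries` so run-wise operations remain possible.
#'
#' @param values numeric matrix, parcels x time. No missing values allowed.
#' @param parcel_ids character vector of unique parcel labels, one per row.
#'   Defaults to `"P001"`, `"P002"`, ...
#' @param tr_seconds sampling interval (TR) in seconds.
#' @param run_boundaries integer vector of time indices at which concatenated
#'   runs start (the first run's start, 1, is always included). Sorted,
#'   within `[1, T]`.
#'
#' @return An object of class `parcel_ts`.
#' @export
parcel_ts <- function(values, parcel_ids = NULL, tr_seconds = 1,
                      run_boundaries = 1L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("parcel time series must not contain missing values")
  if (ncol(values) < 2L) stop("parcel time series needs at least 2 time points")
  if (is.null(parcel_ids)) {
    parcel_ids <- sprintf("P%03d", seq_len(nrow(values)))
  }
  parcel_ids <- as.character(parcel_ids)
  if (length(parcel_ids) != nrow(values)) {
    stop("parcel_ids length (", length(parcel_ids),
         ") does not match number of parcels (", nrow(values), ")")
  }
  if (anyDuplicated(parcel_ids)) stop("duplicate parcel IDs")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be > 0")
  run_boundaries <- sort(unique(as.integer(c(1L, run_boundaries))))
  if (any(run_boundaries < 1L) || any(run_boundaries > ncol(values))) {
    stop("run boundaries must lie within [1, T]")
  }
  rownames(values) <- parcel_ids
  structure(
    list(values = values, parcel_ids = parcel_ids,
         tr_seconds = tr_seconds, run_boundaries = run_boundaries),
    class = "parcel_ts"
  )
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> %d parcels x %d samples, TR = %g s, %d run(s)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds,
              length(x$run_boundaries)))
  invisible(x)
}

#' @export
dim.parcel_ts <- function(x) dim(x$values)

n_parcels <- function(ts) nrow(ts$values)
n_timepoints <- function(ts) ncol(ts$values)

#' Parcel-by-parcel Pearson correlation matrix
#'
#' @param values symmetric numeric matrix with unit diagonal, entries in
#'   `[-1, 1]`.
#' @param parcel_ids labels for rows/columns.
#' @return An object of class `corr_matrix`.
#' @export
corr_matrix <- function(values, parcel_ids = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("correlation matrix must be square")
  if (max(abs(values - t(values))) > 1e-10) stop("correlation matrix must be symmetric")
  if (max(abs(diag(values) - 1)) > 1e-10) stop("correlation matrix must have unit diagonal")
  if (any(values < -1 - 1e-10) || any(values > 1 + 1e-10)) {
    stop("correlation entries must lie in [-1, 1]")
  }
  if (is.null(parcel_ids)) parcel_ids <- sprintf("P%03d", seq_len(n))
  dimnames(values) <- list(parcel_ids, parcel_ids)
  structure(list(values = values, parcel_ids = as.character(parcel_ids)),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix> %d x %d parcels\n", nrow(x$values), nrow(x$values)))
  invisible(x)
}

#' Binary undirected adjacency matrix at a stated edge density
#'
#' @param values binary symmetric matrix with zero diagonal.
#' @param density proportion of possible (unordered) edges retained.
#' @param parcel_ids node labels.
#' @return An object of class `adjacency`.
#' @export
adjacency <- function(values, density, parcel_ids = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("adjacency matrix must be square")
  if (!all(values %in% c(0, 1))) stop("adjacency entries must be 0/1")
  if (any(diag(values) != 0)) stop("adjacency diagonal must be zero")
  if (!isTRUE(all.equal(values, t(values)))) stop("adjacency must be symmetric")
  if (is.null(parcel_ids)) parcel_ids <- sprintf("P%03d", n_seq <- seq_len(n))
  dimnames(values) <- list(parcel_ids, parcel_ids)
  structure(list(values = values, density = density,
                 n = n, parcel_ids = as.character(parcel_ids)),
            class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  m <- sum(x$values) / 2
  cat(sprintf("<adjacency> %d nodes, %d edges (density %.4f)\n",
              x$n, m, x$density))
  invisible(x)
}

#' Per-node centrality vector
#'
#' @param values numeric vector, one entry per node.
#' @param kind `"EC"`, `"PC"` or `"flow"`.
#' @param parcel_ids node labels.
#' @param eigenvalue leading eigenvalue (EC only).
#' @param degrees per-node degree (PC only).
#' @return An object of class `centrality_vector` (a named numeric vector
#'   with attributes).
#' @export
centrality_vector <- function(values, kind, parcel_ids = NULL,
                              eigenvalue = NULL, degrees = NULL) {
  kind <- match.arg(kind, c("EC", "PC", "flow"))
  values <- as.numeric(values)
  if (!is.null(parcel_ids)) names(values) <- parcel_ids
  structure(values, class = "centrality_vector", kind = kind,
            eigenvalue = eigenvalue, degrees = degrees)
}

#' @export
print.centrality_vector <- function(x, ...) {
  cat(sprintf("<centrality_vector> kind=%s, %d nodes\n",
              attr(x, "kind"), length(x)))
  print(utils::head(unclass(x)), ...)
  invisible(x)
}
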