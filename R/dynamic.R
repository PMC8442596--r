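#' Sliding-window specification
#'
#' A rectangular window of `length_seconds` (default 50 s, i.e. 25 s before
#' to 25 s after each centre) advanced one sample at a time. The window
#' length in samples is `round(length_seconds / tr_seconds)`; windows are
#' half-open sample ranges, so with step 1 there are `T - L + 1` windows and
#' the first and last half-window of the scan produce no output.
#'
#' @param length_seconds window length in seconds.
#' @param tr_seconds sampling interval.
#' @param step window step in samples.
#' @return A list of class `window_spec` with `length_samples`.
#' @export
window_spec <- function(length_seconds = 50, tr_seconds = 1, step = 1L) {
  L <- as.integer(round(length_seconds / tr_seconds))
  if (L < 3L) stop("window must span at least 3 samples")
  if (step < 1L) stop("step must be >= 1")
  structure(list(length_seconds = length_seconds, tr_seconds = tr_seconds,
                 step = as.integer(step), length_samples = L),
            class = "window_spec")
}

#' Enumerate sliding windows over a scan
#'
#' @param T number of samples.
#' @param spec a `window_spec`.
#' @return A data.frame with `start`, `end` (inclusive sample indices) and
#'   `center` (the sample index at `start + floor(L/2)`).
#' @export
enumerate_windows <- function(T, spec) {
  stopifnot(inherits(spec, "window_spec"))
  L <- spec$length_samples
  if (T < L) {
    stop("scan of ", T, " samples is shorter than one window (", L,
         " samples)")
  }
  starts <- seq.int(1L, T - L + 1L, by = spec$step)
  data.frame(start = starts, end = starts + L - 1L,
             center = starts + L %/% 2L)
}

#' Time-varying centrality by the sliding-window technique
#'
#' For every window: Pearson correlation of the windowed samples,
#' proportional threshold at the configured edge density, then either
#' eigenvector centrality (tEC) or Louvain communities plus participation
#' coefficient (tPC, communities re-estimated per window from that window's
#' adjacency matrix). Each column of the output therefore equals the static
#' metric computed on that window's samples alone.
#'
#' Windows containing a zero-variance parcel are filled with `NA` and
#' reported in a warning. Per-window Louvain seeds are derived
#' deterministically from `(seed, window index)`.
#'
#' @param ts a `parcel_ts`.
#' @param spec a `window_spec` (its TR must match the data).
#' @param density proportional edge density in `(0, 1]`.
#' @param kind `"EC"` or `"PC"`.
#' @param seed integer seed for per-window Louvain restarts (PC only).
#' @param gamma Louvain resolution (PC only).
#' @param n_restarts Louvain restarts per window (PC only). Fewer than the
#'   static default, since each window is one of hundreds.
#' @return A list of class `tv_centrality` with `values` (parcels x windows
#'   matrix), `centers` (window-centre sample indices), `kind`, `tr_seconds`.
#' @export
time_varying_centrality <- function(ts, spec = window_spec(tr_seconds = ts$tr_seconds),
                                    density = 0.075, kind = c("EC", "PC"),
                                    seed = 1L, gamma = 1, n_restarts = 10L) {
  stopifnot(inherits(ts, "parcel_ts"))
  kind <- match.arg(kind)
  if (abs(spec$tr_seconds - ts$tr_seconds) > 1e-9) {
    stop("window spec TR (", spec$tr_seconds, ") does not match data TR (",
         ts$tr_seconds, ")")
  }
  win <- enumerate_windows(n_timepoints(ts), spec)
  N <- n_parcels(ts)
  W <- nrow(win)
  out <- matrix(NA_real_, N, W, dimnames = list(ts$parcel_ids, NULL))
  flagged <- integer(0)
  for (j in seq_len(W)) {
    seg <- ts$values[, win$start[j]:win$end[j], drop = FALSE]
    sdv <- apply(seg, 1, stats::sd)
    if (any(sdv == 0)) {
      flagged <- c(flagged, j)
      next
    }
    C <- stats::cor(t(seg))
    C <- (C + t(C)) / 2; diag(C) <- 1
    A <- proportional_threshold(corr_matrix(C, ts$parcel_ids), density)
    out[, j] <- if (kind == "EC") {
      as.numeric(eigenvector_centrality(A))
    } else {
      P <- louvain_partition(A, gamma = gamma,
                             seed = as.integer((seed * 10000L + j) %%
                                                 .Machine$integer.max),
                             n_restarts = n_restarts)
      as.numeric(participation_coefficient(A, P))
    }
  }
  if (length(flagged)) {
    warning(length(flagged), " window(s) contained a zero-variance parcel ",
            "and were filled with NA: ",
            paste(utils::head(flagged, 5), collapse = ", "),
            if (length(flagged) > 5) ", ..." else "")
  }
  structure(list(values = out, centers = win$center, kind = kind,
                 tr_seconds = ts$tr_seconds, density = density),
            class = "tv_centrality")
}

#' @export
print.tv_centrality <- function(x, ...) {
  cat(sprintf("<tv_centrality> kind=%s, %d parcels x %d windows (TR %g s)\n",
              x$kind, nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}
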