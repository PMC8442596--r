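#' Fisher z-transform of a correlation coefficient
#'
#' `z = atanh(r)`, the variance-stabilizing transform used before group
#' statistics on correlations.
#'
#' @param r correlation value(s), `|r| < 1`.
#' @return Fisher-z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) stop("|r| must be < 1 for Fisher z")
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher-z value(s).
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Per-parcel correlation with a saliency (or other reference) signal
#'
#' Correlates every parcel's series with the reference signal. For
#' time-varying centrality input the signal is first trimmed to the window
#' centres (sample index alignment), so both series share a time base. An
#' optional lag shifts the signal by `round(lag_s / TR)` samples (positive
#' lag: signal leads).
#'
#' @param x a `parcel_ts`, a `tv_centrality`, or a plain parcels x time
#'   matrix.
#' @param signal a `saliency_signal` or numeric vector sampled at the same
#'   TR; for `parcel_ts`/matrix input it must match the series length after
#'   lagging, for `tv_centrality` it must cover the window-centre indices.
#' @param lag_s lag applied to the signal, in seconds (default 0).
#' @return Named numeric vector of Pearson correlations, one per parcel.
#'   Parcels that are constant over the aligned span give `NA`.
#' @export
parcel_signal_correlation <- function(x, signal, lag_s = 0) {
  if (inherits(x, "tv_centrality")) {
    tr <- x$tr_seconds
    vals <- x$values
    centers <- x$centers
    if (max(centers) > length(signal)) {
      stop("signal too short for window centres: signal length ",
           length(signal), ", last centre ", max(centers))
    }
    sig <- as.numeric(signal)[centers]
  } else {
    vals <- if (inherits(x, "parcel_ts")) x$values else as.matrix(x)
    tr <- if (inherits(x, "parcel_ts")) x$tr_seconds
          else attr(signal, "tr_seconds") %||% 1
    sig <- as.numeric(signal)
    if (length(sig) != ncol(vals)) {
      stop("length mismatch after alignment: series ", ncol(vals),
           ", signal ", length(sig))
    }
  }
  k <- as.integer(round(lag_s / tr))
  if (k != 0L) {
    n <- length(sig)
    if (abs(k) >= n - 2L) stop("lag larger than the series")
    if (k > 0) {
      sig <- sig[1:(n - k)]
      vals <- vals[, (k + 1):n, drop = FALSE]
    } else {
      sig <- sig[(-k + 1):n]
      vals <- vals[, 1:(n + k), drop = FALSE]
    }
  }
  keep <- !is.na(sig)
  vals <- vals[, keep, drop = FALSE]
  sig <- sig[keep]
  if (length(sig) < 10L) stop("need at least 10 aligned samples (have ",
                              length(sig), ")")
  r <- suppressWarnings(as.numeric(stats::cor(t(vals), sig,
                                              use = "pairwise.complete.obs")))
  names(r) <- rownames(vals)
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group-level parcel-wise test with Bonferroni FWE control
#'
#' One-sample t test against zero (e.g. of Fisher-z correlations) or paired
#' t test between two aligned participant x parcel matrices, per parcel.
#' Two-tailed p values are Bonferroni-corrected by `n_tests` and converted
#' to signed standard-normal Z equivalents
#' (`Z = sign(t) * qnorm(1 - p/2)`). The significance flag compares the
#' uncorrected p against `fwe_level / n_tests`, equivalently Z against the
#' configured cutoff `qnorm(1 - fwe_level / n_tests / 2)`.
#'
#' @param values participants x parcels matrix (one-sample mode) or the
#'   first condition (paired mode).
#' @param values2 second condition for `mode = "paired"`.
#' @param mode `"one_sample"` or `"paired"`.
#' @param n_tests number of tests for Bonferroni correction; defaults to
#'   the number of parcels.
#' @param fwe_level family-wise error level (default 0.01).
#' @return A list of class `group_result` with `table` (a data.frame of per
#'   parcel `mean`, `t`, `df`, `p`, `p_corrected`, `Z`, `significant`),
#'   `n_participants`, `n_tests`, `fwe_level`, `z_threshold`, `mode`.
#' @export
group_test <- function(values, values2 = NULL,
                       mode = c("one_sample", "paired"),
                       n_tests = NULL, fwe_level = 0.01) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (mode == "paired") {
    if (is.null(values2)) stop("paired mode needs two value sets")
    values2 <- as.matrix(values2)
    if (!all(dim(values) == dim(values2))) {
      stop("paired value sets must have identical dimensions")
    }
    values <- values - values2
  }
  n <- nrow(values)
  if (n < 3L) stop("need at least 3 participants")
  p_parcels <- ncol(values)
  if (is.null(n_tests)) n_tests <- p_parcels

  mu <- colMeans(values)
  sdv <- apply(values, 2, stats::sd)
  zero_var <- is.na(sdv) | sdv == 0
  se <- sdv / sqrt(n)
  tstat <- ifelse(zero_var, NA_real_, mu / se)
  df <- n - 1L
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p_corr <- pmin(1, p * n_tests)
  # signed normal equivalent of the two-tailed p; cap the quantile argument
  # to keep Z finite for p values below double precision
  Z <- sign(tstat) * stats::qnorm(pmax(p / 2, 1e-300), lower.tail = FALSE)
  z_threshold <- stats::qnorm(fwe_level / n_tests / 2, lower.tail = FALSE)
  sig <- !is.na(p) & p < fwe_level / n_tests
  if (any(zero_var)) {
    warning(sum(zero_var), " parcel(s) had zero or undefined variance ",
            "across participants and were flagged NA")
  }
  tab <- data.frame(
    parcel_id = colnames(values) %||% sprintf("P%03d", seq_len(p_parcels)),
    mean = mu, t = tstat, df = df, p = p, p_corrected = p_corr,
    Z = Z, significant = sig, row.names = NULL
  )
  structure(list(table = tab, n_participants = n, n_tests = n_tests,
                 fwe_level = fwe_level, z_threshold = z_threshold,
                 mode = mode),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf(paste0("<group_result> %s, %d participants, %d tests, ",
                     "FWE %g (Z > %.2f): %d significant parcel(s)\n"),
              x$mode, x$n_participants, x$n_tests, x$fwe_level,
              x$z_threshold, sum(x$table$significant)))
  invisible(x)
}

#' Group-average correlation map via Fisher z
#'
#' Averages per-participant correlations on the Fisher-z scale and
#' back-transforms: `tanh(mean(atanh(r)))` per parcel.
#'
#' @param r_matrix participants x parcels matrix of correlations,
#'   `|r| < 1`.
#' @return Named numeric vector of group-average correlations per parcel.
#' @export
group_average_r_map <- function(r_matrix) {
  r_matrix <- as.matrix(r_matrix)
  if (any(abs(r_matrix) >= 1, na.rm = TRUE)) {
    stop("|r| must be < 1 for Fisher-z averaging")
  }
  tanh(colMeans(atanh(r_matrix)))
}

#' Spatial correlation between two per-parcel maps
#'
#' @param mapA,mapB numeric vectors over the same parcel set (matching
#'   names when named).
#' @return Pearson correlation across parcels.
#' @export
spatial_map_correlation <- function(mapA, mapB) {
  if (length(mapA) != length(mapB)) stop("maps differ in length")
  if (!is.null(names(mapA)) && !is.null(names(mapB)) &&
      !identical(names(mapA), names(mapB))) {
    stop("mismatched parcel IDs between maps")
  }
  if (length(mapA) < 3L) stop("need at least 3 parcels")
  stats::cor(as.numeric(mapA), as.numeric(mapB))
}

#' Compare two independent spatial map correlations
#'
#' Fisher's independent-samples test:
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))` with a two-tailed p.
#'
#' @param r1,r2 the two correlations, `|r| < 1`.
#' @param n number of observations (parcels) underlying each correlation.
#' @return A list with `Z` and `p`.
#' @export
compare_map_correlations <- function(r1, r2, n) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n <= 3) stop("need n > 3")
  Z <- (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))
  list(Z = Z, p = 2 * stats::pnorm(abs(Z), lower.tail = FALSE))
}

#' Per-parcel correlation with a participant-level covariate
#'
#' Correlates a per-participant scalar covariate (e.g. mean head motion)
#' with each parcel's centrality across participants.
#'
#' @param values participants x parcels matrix.
#' @param covariate numeric vector, one value per participant.
#' @return Named numeric vector of correlations per parcel.
#' @export
covariate_correlation <- function(values, covariate) {
  values <- as.matrix(values)
  if (length(covariate) != nrow(values)) {
    stop("covariate length must equal the number of participants")
  }
  if (nrow(values) < 4L) stop("need at least 4 participants")
  if (stats::sd(covariate) == 0) stop("covariate is constant")
  r <- as.numeric(stats::cor(values, covariate))
  names(r) <- colnames(values)
  r
}
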