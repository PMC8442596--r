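#' Pipeline configuration
#'
#' Registry of the tunable parameters of the analysis: proportional edge
#' density (default 7.5%), the candidate densities scanned by the
#' flow-coefficient selection, the 50 s sliding window, movie frame rate,
#' the 0.1 Hz saliency low-pass, Louvain resolution and restarts, the FWE
#' level, and an optional integer-TR lag between signal and centrality.
#'
#' @param density proportional edge density in `(0, 1]`.
#' @param density_candidates candidates for flow-based selection.
#' @param window_seconds sliding-window length.
#' @param tr_seconds sampling interval of the fMRI data.
#' @param fps movie frame rate.
#' @param lowpass_hz saliency low-pass cutoff.
#' @param gamma Louvain resolution.
#' @param seed master seed.
#' @param restarts Louvain restarts for static partitions.
#' @param window_restarts Louvain restarts per sliding window.
#' @param fwe_level family-wise error level.
#' @param lag_s signal lag in seconds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(density = 0.075,
                            density_candidates = c(0.025, 0.05, 0.075,
                                                   0.10, 0.125, 0.15),
                            window_seconds = 50, tr_seconds = 1, fps = 24,
                            lowpass_hz = 0.1, gamma = 1.0, seed = 1L,
                            restarts = 100L, window_restarts = 10L,
                            fwe_level = 0.01, lag_s = 0) {
  stopifnot(density > 0, density <= 1,
            all(density_candidates > 0 & density_candidates <= 1),
            window_seconds > 0, tr_seconds > 0, fps > 0,
            lowpass_hz > 0, fwe_level > 0, fwe_level < 1)
  structure(list(density = density, density_candidates = density_candidates,
                 window_seconds = window_seconds, tr_seconds = tr_seconds,
                 fps = fps, lowpass_hz = lowpass_hz, gamma = gamma,
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 window_restarts = as.integer(window_restarts),
                 fwe_level = fwe_level, lag_s = lag_s),
            class = "pipeline_config")
}

#' Run the full centrality-vs-saliency pipeline on a cohort
#'
#' Executes the whole analysis for each participant: standardize and
#' concatenate runs, correlation matrix, proportional threshold, static EC
#' and PC, sliding-window tEC (and optionally tPC), per-parcel correlation
#' of the time-varying centrality with the reference signal; then the
#' group-level one-sample test of the Fisher-z correlations with Bonferroni
#' FWE control. A manifest records the configuration and seed.
#'
#' @param cohort list of `parcel_ts` (one per participant) or of lists of
#'   runs to be concatenated.
#' @param signal reference signal sampled at the data TR (e.g. a low-pass
#'   filtered `saliency_signal`); when `NULL` the correlation and group
#'   stages are skipped.
#' @param config a `pipeline_config`.
#' @param metrics which time-varying metrics to compute
#'   (`"EC"`, `"PC"`, or both).
#' @param static compute static EC/PC maps per participant (logical).
#' @return A list of class `pipeline_result` with per-participant results
#'   (`correlation`, `adjacency`, `static_ec`, `static_pc`, `tvc`, `r`) and
#'   group results per metric, plus a `manifest`.
#' @export
run_pipeline <- function(cohort, signal = NULL, config = pipeline_config(),
                         metrics = "EC", static = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  metrics <- match.arg(metrics, c("EC", "PC"), several.ok = TRUE)
  n_sub <- length(cohort)
  if (!n_sub) stop("empty cohort")
  wspec <- window_spec(config$window_seconds, config$tr_seconds)
  participants <- vector("list", n_sub)
  r_mats <- stats::setNames(vector("list", length(metrics)), metrics)
  for (p in seq_len(n_sub)) {
    entry <- cohort[[p]]
    ts <- if (inherits(entry, "parcel_ts")) {
      standardize_and_concatenate(list(entry))
    } else {
      standardize_and_concatenate(entry)
    }
    C <- correlation_matrix(ts)
    A <- proportional_threshold(C, config$density)
    res <- list(correlation = C, adjacency = A)
    if (static) {
      res$static_ec <- eigenvector_centrality(A)
      P <- louvain_partition(A, gamma = config$gamma,
                             seed = config$seed + p,
                             n_restarts = config$restarts)
      res$static_pc <- participation_coefficient(A, P)
    }
    res$tvc <- list()
    for (m in metrics) {
      tvc <- time_varying_centrality(ts, wspec, density = config$density,
                                     kind = m, seed = config$seed + p,
                                     gamma = config$gamma,
                                     n_restarts = config$window_restarts)
      res$tvc[[m]] <- tvc
      if (!is.null(signal)) {
        r <- parcel_signal_correlation(tvc, signal, lag_s = config$lag_s)
        r_mats[[m]] <- rbind(r_mats[[m]], r)
      }
    }
    participants[[p]] <- res
  }
  group <- NULL
  if (!is.null(signal)) {
    group <- lapply(r_mats, function(rm) {
      group_test(atanh(rm), mode = "one_sample",
                 n_tests = ncol(rm), fwe_level = config$fwe_level)
    })
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("salnet")),
    config = unclass(config), n_participants = n_sub, metrics = metrics,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(participants = participants, group = group,
                 r_per_participant = r_mats, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d participants, metrics: %s\n",
              length(x$participants),
              paste(x$manifest$metrics, collapse = ", ")))
  if (!is.null(x$group)) {
    for (m in names(x$group)) {
      cat(sprintf("  group t%s: %d significant parcel(s) at FWE %g\n",
                  m, sum(x$group[[m]]$table$significant),
                  x$group[[m]]$fwe_level))
    }
  }
  invisible(x)
}
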