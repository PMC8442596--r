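# TSV dialect: tab-delimited, header row, UTF-8, LF newlines, '.' decimal,
# values written to 12 significant digits.

tsv_write <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
}

#' Write a parcel time series as TSV
#'
#' Layout: one column per parcel (header row of parcel IDs), one row per
#' sample; numeric values at 12 significant digits. TR and run boundaries
#' are recorded in `#`-prefixed comment lines before the header.
#'
#' @param ts a `parcel_ts`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_parcel_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "parcel_ts"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# tr_seconds=%s", format(ts$tr_seconds, digits = 12)),
               sprintf("# run_boundaries=%s",
                       paste(ts$run_boundaries, collapse = ","))),
             con, sep = "\n")
  writeLines(paste(ts$parcel_ids, collapse = "\t"), con, sep = "\n")
  m <- signif(t(ts$values), 12)
  utils::write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a parcel time series from TSV
#'
#' @param path file written by [write_parcel_timeseries()] (or any TSV with
#'   a parcel-ID header row and one row per sample; TR defaults to 1 s when
#'   no comment line records it).
#' @return A `parcel_ts`.
#' @export
read_parcel_timeseries <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  tr <- 1
  boundaries <- 1L
  m_tr <- grep("^# tr_seconds=", meta, value = TRUE)
  if (length(m_tr)) tr <- as.numeric(sub("^# tr_seconds=", "", m_tr[1]))
  m_rb <- grep("^# run_boundaries=", meta, value = TRUE)
  if (length(m_rb)) {
    boundaries <- as.integer(strsplit(sub("^# run_boundaries=", "",
                                          m_rb[1]), ",")[[1]])
  }
  body <- lines[!grepl("^#", lines)]
  ids <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(ids)) stop("duplicate parcel ID column in ", path)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  vals <- vapply(rows, function(r) {
    x <- suppressWarnings(as.numeric(r))
    if (anyNA(x)) stop("non-numeric cell in ", path)
    if (length(x) != length(ids)) stop("ragged row in ", path)
    x
  }, numeric(length(ids)))
  parcel_ts(vals, parcel_ids = ids, tr_seconds = tr,
            run_boundaries = boundaries)
}

#' Write a square matrix (correlation or adjacency) as TSV
#'
#' @param x a `corr_matrix`, `adjacency`, or plain matrix.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(x, path) {
  M <- if (inherits(x, c("corr_matrix", "adjacency"))) x$values else as.matrix(x)
  df <- data.frame(parcel_id = rownames(M) %||% sprintf("P%03d", seq_len(nrow(M))),
                   signif(M, 12), check.names = FALSE)
  colnames(df) <- c("parcel_id",
                    rownames(M) %||% sprintf("P%03d", seq_len(nrow(M))))
  tsv_write(df, path)
  invisible(path)
}

#' Read a square matrix written by [write_matrix_tsv()]
#'
#' @param path file path.
#' @return A numeric matrix with parcel IDs as dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  dimnames(M) <- list(ids, ids)
  M
}

#' Write a saliency signal as two-column TSV (time_s, saliency)
#'
#' @param signal a `saliency_signal`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_saliency_signal <- function(signal, path) {
  stopifnot(inherits(signal, "saliency_signal"))
  tr <- attr(signal, "tr_seconds")
  tsv_write(data.frame(time_s = (seq_along(signal) - 1) * tr,
                       saliency = signif(as.numeric(signal), 12)), path)
  invisible(path)
}

#' Write a group-result table as TSV with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records `n_participants`, `n_tests`,
#' `fwe_level` and the configured Z threshold.
#'
#' @param result a `group_result`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_group_result <- function(result, path) {
  stopifnot(inherits(result, "group_result"))
  tsv_write(result$table, path)
  jsonlite::write_json(
    list(mode = result$mode, n_participants = result$n_participants,
         n_tests = result$n_tests, fwe_level = result$fwe_level,
         z_threshold = result$z_threshold),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write generator ground truth as JSON
#'
#' @param truth ground-truth list from the synthetic-data generators
#'   (community labels, coupled parcels, driver).
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
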