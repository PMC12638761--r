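#' @include synthetic.R
NULL

#' Write / read a labelled square network TSV
#'
#' Square tab-separated matrix with ROI labels as header row and first
#' column.
#'
#' @param w square numeric matrix (rows/columns named, or labels supplied).
#' @param path file path.
#' @param roiLabels optional labels when \code{w} is unnamed.
#' @return \code{path} invisibly (write); numeric matrix (read).
#' @export
writeNetworkTsv <- function(w, path, roiLabels = NULL) {
  w <- as.matrix(w)
  if (is.null(rownames(w))) {
    if (is.null(roiLabels)) roiLabels <- paste0("ROI", seq_len(nrow(w)))
    dimnames(w) <- list(roiLabels, roiLabels)
  }
  df <- data.frame(roi = rownames(w), w, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNetworkTsv
#' @export
readNetworkTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read ROI time series with a JSON sidecar
#'
#' The TSV holds one ROI per row and one sample per column (no header); the
#' sidecar JSON provides \code{sample_rate} (Hz) and optional \code{labels}.
#'
#' @param tsvPath path to the time-series TSV.
#' @param jsonPath sidecar path; defaults to \code{tsvPath} with a
#'   \code{.json} extension.
#' @return list with \code{timeseries} (matrix), \code{sampleRate},
#'   \code{roiLabels}.
#' @export
readRoiTimeseries <- function(tsvPath, jsonPath = sub("\\.tsv$", ".json", tsvPath)) {
  ts <- as.matrix(read.delim(tsvPath, header = FALSE))
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  labels <- if (!is.null(meta$labels)) as.character(meta$labels)
            else paste0("ROI", seq_len(nrow(ts)))
  list(timeseries = unname(ts), sampleRate = as.numeric(meta$sample_rate),
       roiLabels = labels)
}

# tidy long-format metric table (participant, band, metric, roi, value)
.tidyMetrics <- function(metricsByBand, ids) {
  rows <- list()
  for (band in names(metricsByBand)) {
    m <- metricsByBand[[band]]
    rows[[length(rows) + 1L]] <- data.frame(
      participant = ids, band = band, metric = "global_efficiency",
      roi = NA_character_, value = m$E, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      participant = ids, band = band, metric = "global_clustering",
      roi = NA_character_, value = m$C, stringsAsFactors = FALSE)
    lab <- colnames(m$Ei)
    if (is.null(lab)) lab <- paste0("ROI", seq_len(ncol(m$Ei)))
    for (j in seq_along(lab)) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant = ids, band = band, metric = "nodal_efficiency",
        roi = lab[j], value = m$Ei[, j], stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = ids, band = band, metric = "local_clustering",
        roi = lab[j], value = m$Ci[, j], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
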