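#' Region-level time series block
#'
#' Container for source-level band-limited signals: a regions x samples numeric
#' matrix with a sampling rate. This is the unit every connectivity operation
#' consumes; row order defines region order everywhere downstream.
#'
#' @param data numeric matrix, regions in rows, samples in columns
#' @param fs sampling rate in Hz
#' @param labels character vector of unique region names; defaults to
#'   `rownames(data)` or `R1..Rn`
#' @param band optional band tag (a [band_definition()]) carried for bookkeeping
#' @return an object of class `region_ts`
#' @export
region_ts <- function(data, fs, labels = NULL, band = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) {
    stop_plvnet("region_ts: data must be a finite numeric matrix")
  }
  if (!is_scalar_number(fs) || fs <= 0) stop_plvnet("region_ts: fs must be a positive number")
  if (is.null(labels)) {
    labels <- rownames(data)
    if (is.null(labels)) labels <- paste0("R", seq_len(nrow(data)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) stop_plvnet("region_ts: one label per region required")
  if (anyDuplicated(labels)) stop_plvnet("region_ts: region labels must be unique")
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels, band = band),
    class = "region_ts"
  )
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf(
    "<region_ts> %d regions x %d samples @ %g Hz (%.1f s)%s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    if (!is.null(x$band)) paste0(", band ", x$band$name) else ""
  ))
  invisible(x)
}

n_regions <- function(ts) nrow(ts$data)
n_samples <- function(ts) ncol(ts$data)
duration_s <- function(ts) ncol(ts$data) / ts$fs

#' Write / read a region time-series matrix as CSV with a JSON sidecar
#'
#' The CSV holds samples in columns and one labelled row per region; the
#' sidecar (`<path>.json`) records the sampling rate and band tag so a file
#' round-trips into an identical object.
#'
#' @param ts a [region_ts()]
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_region_ts <- function(ts, path) {
  utils::write.csv(data.frame(region = ts$labels, ts$data, check.names = FALSE),
    path,
    row.names = FALSE
  )
  side <- list(fs = ts$fs, band = if (is.null(ts$band)) NULL else unclass(ts$band))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_region_ts
#' @export
read_region_ts <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- unname(as.matrix(df[, -1, drop = FALSE]))
  band <- if (!is.null(side$band) && length(side$band)) {
    band_definition(side$band$name, side$band$lo, side$band$hi)
  } else {
    NULL
  }
  region_ts(m, fs = side$fs, labels = df[[1]], band = band)
}
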