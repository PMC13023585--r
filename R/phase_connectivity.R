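#' EEG frequency band definition
#'
#' @param name band label
#' @param lo,hi band edges in Hz, `0 < lo < hi`
#' @return object of class `band_definition`
#' @export
band_definition <- function(name, lo, hi) {
  if (!is_scalar_number(lo) || !is_scalar_number(hi) || lo <= 0 || hi <= lo) {
    stop_plvnet("band_definition: need 0 < lo < hi")
  }
  structure(list(name = as.character(name), lo = lo, hi = hi),
    class = "band_definition"
  )
}

#' The canonical theta/alpha/beta analysis bands
#'
#' Theta 4-8 Hz, alpha 8-14 Hz, beta 14-30 Hz.
#'
#' @return named list of [band_definition()] objects
#' @export
default_bands <- function() {
  list(
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 14),
    beta  = band_definition("beta", 14, 30)
  )
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (`signal::filtfilt`) so
#' the output has no group delay. The default order gives >= 20 dB attenuation
#' one octave-ish outside the passband after the two passes.
#'
#' @param ts a [region_ts()]
#' @param band a [band_definition()]; `hi` must be below the Nyquist frequency
#' @param order Butterworth order per pass (default 4; effective 8 after
#'   forward-backward filtering)
#' @return a [region_ts()] of identical shape, tagged with `band`
#' @export
bandpass <- function(ts, band, order = 4) {
  stopifnot(inherits(ts, "region_ts"), inherits(band, "band_definition"))
  nyq <- ts$fs / 2
  if (band$hi >= nyq) {
    stop_plvnet(sprintf(
      "bandpass: band [%g, %g] Hz reaches the Nyquist frequency (%g Hz)",
      band$lo, band$hi, nyq
    ))
  }
  bf <- signal::butter(order, c(band$lo, band$hi) / nyq, type = "pass")
  filtered <- t(apply(ts$data, 1, function(x) signal::filtfilt(bf, x)))
  region_ts(filtered, fs = ts$fs, labels = ts$labels, band = band)
}

#' Cut a recording into fixed-length non-overlapping segments
#'
#' Consecutive windows of exactly `seg_seconds`; a trailing remainder shorter
#' than one window is discarded, so the count is
#' `floor(duration / seg_seconds)`.
#'
#' @param ts a [region_ts()]
#' @param seg_seconds segment length in seconds (default 6)
#' @return list of [region_ts()] segments
#' @export
segment_ts <- function(ts, seg_seconds = 6) {
  stopifnot(inherits(ts, "region_ts"))
  seg_len <- floor(seg_seconds * ts$fs)
  n <- n_samples(ts)
  k <- n %/% seg_len
  if (k < 1L) {
    stop_plvnet(sprintf(
      "segment_ts: recording (%.2f s) shorter than one %g s segment",
      duration_s(ts), seg_seconds
    ))
  }
  lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * seg_len + 1L):(i * seg_len)
    region_ts(ts$data[, idx, drop = FALSE],
      fs = ts$fs,
      labels = ts$labels, band = ts$band
    )
  })
}

#' Analytic signal of a real vector via the frequency-domain Hilbert method
#'
#' Doubles positive frequencies and zeroes negative ones, keeping DC (and
#' Nyquist for even lengths) untouched, then inverse-transforms.
#'
#' @param x real numeric vector
#' @return complex vector whose argument is the instantaneous phase
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 2L)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2L:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of band-limited signals
#'
#' Per-region analytic-signal phase in `(-pi, pi]`. Signals must carry power:
#' an all-zero region has no defined phase and is rejected.
#'
#' @param ts a band-limited [region_ts()] (typically one segment after
#'   [bandpass()])
#' @return numeric matrix of phases, regions x samples
#' @export
instantaneous_phase <- function(ts) {
  stopifnot(inherits(ts, "region_ts"))
  dead <- which(apply(ts$data, 1, function(x) all(x == 0)))
  if (length(dead)) {
    stop_plvnet(sprintf(
      "instantaneous_phase: all-zero signal for region(s) %s (phase undefined)",
      paste(ts$labels[dead], collapse = ", ")
    ))
  }
  t(apply(ts$data, 1, function(x) Arg(analytic_signal(x))))
}

#' Phase locking value of two phase series
#'
#' Modulus of the time-averaged unit phasor of the phase difference:
#' `|mean(exp(i (phase_x - phase_y)))|`. 1 means rigid phase locking, 0 no
#' consistent phase relation. Symmetric in its arguments and invariant to a
#' constant phase offset in either series.
#'
#' @param phase_x,phase_y phase series in radians, equal length >= 2
#' @return a value in `[0, 1]`
#' @export
plv <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) {
    stop_plvnet("plv: phase series lengths differ")
  }
  stopifnot(length(phase_x) >= 2L)
  Mod(mean(exp(1i * (phase_x - phase_y))))
}

#' Symmetric PLV connectivity matrix
#'
#' Container for a band-specific PLV matrix: values in `[0, 1]`, symmetric,
#' diagonal stored as 1 (self-connections are excluded from all downstream
#' statistics).
#'
#' @param values symmetric numeric matrix of PLV
#' @param labels region labels
#' @param band a [band_definition()] or NULL
#' @param n_segments number of segments averaged
#' @return object of class `plv_matrix`
#' @export
plv_matrix <- function(values, labels = NULL, band = NULL, n_segments = NA_integer_) {
  values <- as.matrix(values)
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("R", seq_len(nrow(values)))
  }
  if (nrow(values) != ncol(values)) stop_plvnet("plv_matrix: matrix must be square")
  if (any(!is.finite(values))) stop_plvnet("plv_matrix: non-finite values")
  if (max(abs(values - t(values))) > 1e-10) stop_plvnet("plv_matrix: matrix must be symmetric")
  if (min(values) < -1e-10 || max(values) > 1 + 1e-10) {
    stop_plvnet("plv_matrix: PLV values must lie in [0, 1]")
  }
  values <- pmin(pmax((values + t(values)) / 2, 0), 1)
  diag(values) <- 1
  dimnames(values) <- list(labels, labels)
  structure(
    list(
      values = values, labels = as.character(labels), band = band,
      n_segments = as.integer(n_segments)
    ),
    class = "plv_matrix"
  )
}

#' @export
print.plv_matrix <- function(x, ...) {
  cat(sprintf(
    "<plv_matrix> %d regions%s, %s segments, mean off-diagonal PLV %.3f\n",
    length(x$labels),
    if (!is.null(x$band)) paste0(", band ", x$band$name) else "",
    ifelse(is.na(x$n_segments), "?", x$n_segments),
    total_average_plv(x)
  ))
  invisible(x)
}

per_segment_plv <- function(phases, trim = 0.05) {
  nt <- ncol(phases)
  keep <- seq.int(floor(nt * trim) + 1L, nt - floor(nt * trim))
  z <- exp(1i * phases[, keep, drop = FALSE])
  m <- (z %*% Conj(t(z))) / length(keep)
  Mod(m)
}

#' Band-specific PLV connectivity from region time series
#'
#' The full measurement pipeline: band-pass filter, cut into `seg_seconds`
#' segments, extract analytic-signal phases per segment, compute PLV for every
#' region pair per segment (trimming `edge_trim` of the samples at each segment
#' edge against filter/Hilbert transients), then average PLV across segments.
#'
#' @param ts a broadband or band-limited [region_ts()]
#' @param band a [band_definition()]
#' @param seg_seconds segment length in seconds (default 6)
#' @param edge_trim fraction of samples dropped at each end of every segment
#'   before phase averaging (default 0.05)
#' @return a [plv_matrix()]
#' @export
connectivity_matrix <- function(ts, band, seg_seconds = 6, edge_trim = 0.05) {
  filtered <- bandpass(ts, band)
  segs <- segment_ts(filtered, seg_seconds)
  acc <- 0
  for (s in segs) {
    acc <- acc + per_segment_plv(instantaneous_phase(s), trim = edge_trim)
  }
  vals <- acc / length(segs)
  diag(vals) <- 1
  plv_matrix(vals, labels = ts$labels, band = band, n_segments = length(segs))
}

#' Write / read a PLV matrix as labelled CSV with a JSON sidecar
#'
#' @param W a [plv_matrix()]
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_plv_matrix <- function(W, path) {
  utils::write.csv(
    data.frame(region = W$labels, W$values, check.names = FALSE),
    path,
    row.names = FALSE
  )
  side <- list(
    band = if (is.null(W$band)) NULL else unclass(W$band),
    n_segments = W$n_segments
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plv_matrix
#' @export
read_plv_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  side_path <- paste0(path, ".json")
  band <- NULL
  nseg <- NA_integer_
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$band) && length(side$band)) {
      band <- band_definition(side$band$name, side$band$lo, side$band$hi)
    }
    if (!is.null(side$n_segments)) nseg <- as.integer(side$n_segments)
  }
  plv_matrix(m, labels = df[[1]], band = band, n_segments = nseg)
}
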