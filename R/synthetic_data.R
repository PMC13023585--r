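#' Specification of a phase-coupled oscillator ensemble
#'
#' Describes one band-limited surrogate recording: how many regions, which
#' band, sampling rate, duration, and the target pairwise PLV matrix. Targets
#' are realized by mixing white-noise sources with a latent correlation
#' structure and measuring PLV through the actual band-pass/segment/phase
#' pipeline, so the generator is calibrated against the estimator it feeds.
#'
#' @param n_regions number of regions (default 78)
#' @param band a [band_definition()]
#' @param fs sampling rate in Hz (default 256); must exceed twice the band's
#'   upper edge
#' @param duration recording length in seconds
#' @param coupling symmetric matrix of target PLV in `[0, 1]` with unit
#'   diagonal; default identity (independent regions)
#' @param seed integer seed
#' @param labels optional region labels
#' @return object of class `oscillator_spec`
#' @export
oscillator_spec <- function(n_regions = 78, band, fs = 256, duration,
                            coupling = NULL, seed = 1L, labels = NULL) {
  stopifnot(inherits(band, "band_definition"))
  if (fs <= 2 * band$hi) {
    stop_plvnet(sprintf(
      "oscillator_spec: fs = %g Hz must exceed twice the band upper edge (%g Hz)",
      fs, band$hi
    ))
  }
  if (is.null(coupling)) coupling <- diag(n_regions)
  coupling <- as.matrix(coupling)
  if (nrow(coupling) != n_regions || ncol(coupling) != n_regions) {
    stop_plvnet("oscillator_spec: coupling must be n_regions x n_regions")
  }
  if (max(abs(coupling - t(coupling))) > 1e-12) {
    stop_plvnet("oscillator_spec: coupling must be symmetric")
  }
  if (any(abs(diag(coupling) - 1) > 1e-12)) {
    stop_plvnet("oscillator_spec: coupling diagonal must be exactly 1")
  }
  off <- coupling[upper.tri(coupling)]
  if (any(off < 0 | off > 1)) {
    stop_plvnet("oscillator_spec: off-diagonal coupling must lie in [0, 1]")
  }
  if (is.null(labels)) labels <- paste0("R", seq_len(n_regions))
  structure(
    list(
      n_regions = as.integer(n_regions), band = band, fs = fs,
      duration = duration, coupling = coupling, seed = as.integer(seed),
      labels = as.character(labels)
    ),
    class = "oscillator_spec"
  )
}

# Memoised simulation-oracle evaluations live here for the session.
.calib_cache <- new.env(parent = emptyenv())

calib_key <- function(band, fs, seg_seconds, n_segments, n_reps) {
  sprintf(
    "%g-%g|fs%g|seg%g|n%d|reps%d",
    band$lo, band$hi, fs, seg_seconds, as.integer(n_segments), as.integer(n_reps)
  )
}

simulate_pair_once <- function(r, band, fs, n_segments, seg_seconds, seed) {
  nt <- as.integer(round(n_segments * seg_seconds * fs))
  x <- with_seed(seed, matrix(stats::rnorm(2L * nt), nrow = 2L))
  mix <- rbind(
    c(1, 0),
    c(r, sqrt(max(0, 1 - r^2)))
  )
  ts <- region_ts(mix %*% x, fs = fs)
  W <- connectivity_matrix(ts, band, seg_seconds = seg_seconds)
  W$values[1, 2]
}

#' Simulation oracle: expected empirical PLV of a pair at latent correlation r
#'
#' Simulates `n_reps` two-region recordings whose band-limited signals share
#' latent correlation `r`, runs each through [connectivity_matrix()], and
#' averages the measured PLV. Memoised per configuration; the map is monotone
#' nondecreasing in `r` up to Monte-Carlo noise.
#'
#' @param r latent correlation in `[0, 1]`
#' @param band,fs,seg_seconds measurement configuration
#' @param n_segments number of 6-s segments the measurement averages over
#' @param n_reps Monte-Carlo repetitions (default 4)
#' @param seed base seed for the oracle simulations
#' @return mean empirical PLV
#' @export
plv_response <- function(r, band, fs = 256, seg_seconds = 6, n_segments = 50,
                         n_reps = 4, seed = 761L) {
  stopifnot(r >= 0, r <= 1)
  if (r >= 1) return(1)
  key <- paste0(calib_key(band, fs, seg_seconds, n_segments, n_reps), "|r", round(r, 6))
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  seeds <- derive_seeds(seed + round(r * 1e6) %% 1000L, n_reps)
  val <- mean(vapply(
    seeds,
    function(s) simulate_pair_once(r, band, fs, n_segments, seg_seconds, s),
    numeric(1)
  ))
  .calib_cache[[key]] <- val
  val
}

#' Finite-sample PLV floor under zero coupling
#'
#' The expected empirical PLV of two independent regions for a given
#' measurement configuration (per-segment Rayleigh-type bias, essentially flat
#' in the number of segments because segment PLV moduli are averaged).
#' Estimated by the simulation oracle at latent correlation 0.
#'
#' @inheritParams plv_response
#' @return expected zero-coupling PLV
#' @export
plv_floor <- function(band, fs = 256, seg_seconds = 6, n_segments = 50,
                      n_reps = 6, seed = 761L) {
  plv_response(0, band, fs, seg_seconds, n_segments, n_reps = n_reps, seed = seed)
}

#' Calibrate a target PLV to a latent mixing weight
#'
#' Monotone bisection of the simulation oracle [plv_response()]: finds the
#' latent correlation (mixing weight) whose expected measured PLV matches the
#' target to within `tol`. A target of 1 maps to weight 1 exactly; targets
#' below the finite-sample floor are unreachable and raise an error reporting
#' the floor.
#'
#' @param target_plv target PLV in `[0, 1]`
#' @inheritParams plv_response
#' @param tol calibration tolerance on the PLV scale (default 0.01)
#' @return latent correlation weight in `[0, 1]`
#' @export
calibrate_coupling <- function(target_plv, n_segments = 50, band = default_bands()$alpha,
                               fs = 256, seg_seconds = 6, tol = 0.01,
                               n_reps = 4, seed = 761L) {
  stopifnot(target_plv >= 0, target_plv <= 1)
  if (target_plv >= 1) return(1)
  floor_plv <- plv_floor(band, fs, seg_seconds, n_segments, seed = seed)
  if (target_plv < floor_plv - tol) {
    stop_plvnet(sprintf(
      "calibrate_coupling: target PLV %.3f is below the finite-sample floor %.3f for this configuration",
      target_plv, floor_plv
    ))
  }
  if (target_plv <= floor_plv) return(0)
  lo <- 0
  hi <- 1
  f_lo <- floor_plv
  f_hi <- 1
  for (i in 1:12) {
    mid <- (lo + hi) / 2
    f_mid <- plv_response(mid, band, fs, seg_seconds, n_segments, n_reps, seed)
    if (abs(f_mid - target_plv) <= tol / 2) return(mid)
    if (f_mid < target_plv) {
      lo <- mid
      f_lo <- f_mid
    } else {
      hi <- mid
      f_hi <- f_mid
    }
    if (hi - lo < 1e-3) break
  }
  # linear interpolation inside the final bracket
  if (f_hi > f_lo) lo + (hi - lo) * (target_plv - f_lo) / (f_hi - f_lo) else (lo + hi) / 2
}

#' Calibration curve target PLV -> latent weight for a measurement setup
#'
#' Evaluates the simulation oracle on a grid of latent correlations, enforces
#' monotonicity (isotonic pass), and returns an invertible interpolator. Used
#' by the group generator so that a whole matrix of heterogeneous targets needs
#' one curve rather than one bisection per entry.
#'
#' @inheritParams plv_response
#' @param grid latent correlation grid
#' @return list with `floor` (zero-coupling PLV), and `to_weight(target)`
#'   mapping PLV targets to latent weights (targets at/below the floor map to
#'   0, target 1 maps to 1)
#' @export
calibration_curve <- function(band, fs = 256, seg_seconds = 6, n_segments = 50,
                              n_reps = 4, seed = 761L,
                              grid = seq(0, 1, by = 0.05)) {
  resp <- vapply(
    grid,
    function(r) plv_response(r, band, fs, seg_seconds, n_segments, n_reps, seed),
    numeric(1)
  )
  resp[length(resp)] <- 1
  resp <- cummax(resp) # isotonic: MC noise must not break invertibility
  floor_plv <- resp[1]
  to_weight <- function(target) {
    vapply(target, function(tv) {
      if (tv >= 1) return(1)
      if (tv <= floor_plv) return(0)
      stats::approx(resp, grid, xout = tv, ties = "ordered")$y
    }, numeric(1))
  }
  list(floor = floor_plv, grid = grid, response = resp, to_weight = to_weight)
}

#' Map a target-PLV coupling matrix to a latent correlation matrix
#'
#' Applies a calibration curve entrywise and checks joint realizability: the
#' latent matrix must be positive semidefinite. On failure the error names an
#' offending region triple whose 3x3 principal minor is negative.
#'
#' @param coupling symmetric target-PLV matrix with unit diagonal
#' @param curve a [calibration_curve()]
#' @return latent correlation matrix
#' @keywords internal
latent_corr_matrix <- function(coupling, curve) {
  n <- nrow(coupling)
  R <- diag(n)
  ut <- upper.tri(coupling)
  R[ut] <- curve$to_weight(coupling[ut])
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    bad <- find_infeasible_triple(R)
    if (!is.null(bad)) {
      stop_plvnet(sprintf(
        "coupling targets not jointly realizable by the mixing model: offending triple (%d, %d, %d) has a negative 3x3 correlation minor",
        bad[1], bad[2], bad[3]
      ))
    }
    stop_plvnet(sprintf(
      "coupling targets not jointly realizable by the mixing model (latent matrix has minimum eigenvalue %.3g)",
      min(ev)
    ))
  }
  R
}

find_infeasible_triple <- function(R) {
  n <- nrow(R)
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        if (det(R[c(i, j, k), c(i, j, k)]) < -1e-10) {
          return(c(i, j, k))
        }
      }
    }
  }
  NULL
}

corr_mixing_root <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Simulate phase-coupled region signals
#'
#' Generates broadband region signals whose band-limited pairwise PLV —
#' measured by [connectivity_matrix()] on 6-s segments — approaches the
#' spec's coupling targets: white-noise sources are mixed through the square
#' root of the calibrated latent correlation matrix. Deterministic given the
#' spec's seed.
#'
#' @param spec an [oscillator_spec()]
#' @param curve optional pre-computed [calibration_curve()] matching the
#'   spec's band/fs/duration; computed on the fly if omitted
#' @param seg_seconds segment length the coupling is calibrated for (default 6)
#' @return a [region_ts()]
#' @export
simulate_region_signals <- function(spec, curve = NULL, seg_seconds = 6) {
  stopifnot(inherits(spec, "oscillator_spec"))
  n_segments <- floor(spec$duration / seg_seconds)
  if (n_segments < 1) stop_plvnet("simulate_region_signals: duration below one segment")
  if (is.null(curve)) {
    curve <- calibration_curve(spec$band,
      fs = spec$fs, seg_seconds = seg_seconds,
      n_segments = n_segments
    )
  }
  R <- latent_corr_matrix(spec$coupling, curve)
  L <- corr_mixing_root(R)
  nt <- as.integer(round(spec$duration * spec$fs))
  W <- with_seed(spec$seed, matrix(stats::rnorm(spec$n_regions * nt), nrow = spec$n_regions))
  region_ts(L %*% W, fs = spec$fs, labels = spec$labels, band = spec$band)
}
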