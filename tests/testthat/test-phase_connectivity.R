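fs <- 256

sine_ts <- function(freq, dur = 10, fs. = fs, n_chan = 1) {
  t <- seq_len(dur * fs.) / fs.
  region_ts(matrix(rep(cos(2 * pi * freq * t), n_chan), nrow = n_chan, byrow = TRUE), fs.)
}

test_that("band-pass keeps in-band sinusoids and attenuates out-of-band ones by >= 20 dB", {
  x <- sine_ts(10)
  in_band <- bandpass(x, default_bands()$alpha)
  # compare RMS away from the filter edges
  core <- 257:(ncol(x$data) - 256)
  ratio_in <- sd(in_band$data[1, core]) / sd(x$data[1, core])
  expect_gt(ratio_in, 0.95)
  expect_lt(ratio_in, 1.05)

  out_band <- bandpass(x, default_bands()$theta)
  ratio_out <- sd(out_band$data[1, core]) / sd(x$data[1, core])
  expect_lt(20 * log10(ratio_out), -20)
})

test_that("band-pass concentrates white-noise variance inside the band", {
  set.seed(11)
  ts <- region_ts(matrix(rnorm(fs * 30), nrow = 1), fs)
  filt <- bandpass(ts, default_bands()$beta)
  spec <- stats::spec.pgram(as.numeric(filt$data[1, ]),
    taper = 0, plot = FALSE, detrend = FALSE
  )
  hz <- spec$freq * fs
  in_band <- hz >= 14 & hz <= 30
  expect_gt(sum(spec$spec[in_band]) / sum(spec$spec), 0.95)
})

test_that("bands at or above Nyquist are rejected", {
  x <- sine_ts(10)
  expect_error(bandpass(x, band_definition("wide", 30, 130)), "Nyquist")
})

test_that("segmentation yields floor(duration/6) non-overlapping 6-s windows", {
  long <- sine_ts(10, dur = 300)
  segs <- segment_ts(long, 6)
  expect_length(segs, 50)
  expect_true(all(vapply(segs, function(s) ncol(s$data), numeric(1)) == 6 * fs))
  # segments tile the recording without overlap
  recon <- do.call(cbind, lapply(segs, function(s) s$data))
  expect_identical(recon, long$data[, seq_len(50 * 6 * fs), drop = FALSE])

  expect_length(segment_ts(sine_ts(10, dur = 6)), 1)
  expect_length(segment_ts(sine_ts(10, dur = 11.9)), 1)
  expect_error(segment_ts(sine_ts(10, dur = 3)), "shorter than one")
})

test_that("analytic-signal phase advances at 2*pi*f for a pure sinusoid", {
  x <- sine_ts(10, dur = 8)
  ph <- instantaneous_phase(x)
  core <- 200:(ncol(ph) - 200)
  unwrapped <- cumsum(c(ph[1, core[1]], {
    d <- diff(ph[1, core])
    d[d < -pi] <- d[d < -pi] + 2 * pi
    d[d > pi] <- d[d > pi] - 2 * pi
    d
  }))
  slope <- stats::coef(stats::lm(unwrapped ~ seq_along(unwrapped)))[2] * fs
  expect_lt(abs(slope - 2 * pi * 10) / (2 * pi * 10), 0.01)
})

test_that("quadrature pair has constant pi/2 phase difference and amplitude does not change phase", {
  t <- seq_len(8 * fs) / fs
  ts2 <- region_ts(rbind(cos(2 * pi * 10 * t), sin(2 * pi * 10 * t)), fs)
  ph <- instantaneous_phase(ts2)
  core <- 200:(ncol(ph) - 200)
  d <- ph[1, core] - ph[2, core]
  d <- atan2(sin(d), cos(d))
  expect_true(all(abs(d - pi / 2) < 0.02))

  ts_scaled <- region_ts(rbind(cos(2 * pi * 10 * t), 7.3 * cos(2 * pi * 10 * t)), fs)
  ph2 <- instantaneous_phase(ts_scaled)
  expect_equal(ph2[1, ], ph2[2, ], tolerance = 1e-10)
})

test_that("all-zero signals are rejected by phase extraction", {
  z <- region_ts(rbind(rep(0, 512), rnorm(512)), fs, labels = c("dead", "ok"))
  expect_error(instantaneous_phase(z), "dead")
})

test_that("plv obeys its closed-form and Rayleigh null properties", {
  ph <- runif(500, -pi, pi)
  expect_equal(plv(ph, ph), 1)

  # phase differences alternating 0, pi in equal number cancel exactly
  x <- rep(0, 100)
  y <- rep(c(0, pi), 50)
  expect_equal(plv(x, y), 0, tolerance = 1e-12)

  expect_error(plv(ph, ph[-1]), "lengths differ")

  # E[PLV^2] = 1/T for independent uniform phases (Rayleigh)
  set.seed(21)
  T_len <- 64
  n_rep <- 4000
  plv2 <- replicate(n_rep, plv(runif(T_len, -pi, pi), runif(T_len, -pi, pi))^2)
  se <- sd(plv2) / sqrt(n_rep)
  expect_lt(abs(mean(plv2) - 1 / T_len), 4 * se)
})

test_that("plv is symmetric and invariant to constant phase offsets (property sweep)", {
  set.seed(31)
  for (rep in 1:20) {
    a <- runif(200, -pi, pi)
    b <- runif(200, -pi, pi)
    off <- runif(1, -10, 10)
    v <- plv(a, b)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(v, plv(b, a), tolerance = 1e-12)
    expect_equal(v, plv(a + off, b), tolerance = 1e-10)
  }
})

test_that("connectivity_matrix: duplicated channels lock at 1, independent channels sit near the floor, output is deterministic", {
  set.seed(41)
  base <- rnorm(60 * fs)
  dup <- region_ts(rbind(base, base, rnorm(60 * fs)), fs, labels = c("a", "b", "c"))
  W <- connectivity_matrix(dup, test_band())
  expect_equal(W$values[1, 2], 1, tolerance = 1e-9)
  expect_equal(W$n_segments, 10L)
  expect_true(isSymmetric(W$values))
  expect_true(all(diag(W$values) == 1))

  # independent channels: off-diagonal PLV near the zero-coupling floor
  fl <- plv_floor(test_band(), n_segments = 10)
  expect_lt(abs(W$values[1, 3] - fl), 0.12)

  W2 <- connectivity_matrix(dup, test_band())
  expect_identical(W$values, W2$values)
})

test_that("segment-averaged PLV of a coupled pair tightens as 1/sqrt(n_segments)", {
  band <- test_band()
  sds <- vapply(c(10, 200), function(nseg) {
    vals <- vapply(1:10, function(r) {
      sim <- with(
        list(w = 0.6),
        {
          nt <- nseg * 6 * fs
          x <- plvnet:::with_seed(1000 + nseg * 7 + r, matrix(rnorm(2 * nt), 2))
          mix <- rbind(c(1, 0), c(0.6, sqrt(1 - 0.36)))
          region_ts(mix %*% x, fs)
        }
      )
      connectivity_matrix(sim, band)$values[1, 2]
    }, numeric(1))
    sd(vals)
  }, numeric(1))
  # expected ratio sqrt(200/10) ~ 4.5; allow wide MC slack but require decrease
  expect_gt(sds[1] / sds[2], 1.8)
})

test_that("PLV matrices and region series round-trip through CSV", {
  set.seed(51)
  ts <- region_ts(matrix(rnorm(3 * 100), 3), fs, labels = c("x", "y", "z"))
  f <- tempfile(fileext = ".csv")
  write_region_ts(ts, f)
  back <- read_region_ts(f)
  expect_equal(back$data, ts$data, tolerance = 1e-12)
  expect_identical(back$labels, ts$labels)

  m <- random_symmetric_weights(4, 3)
  W <- plv_matrix(m, labels = letters[1:4], band = test_band(), n_segments = 5L)
  f2 <- tempfile(fileext = ".csv")
  write_plv_matrix(W, f2)
  back2 <- read_plv_matrix(f2)
  expect_equal(back2$values, W$values, tolerance = 1e-12)
  expect_identical(back2$n_segments, 5L)
  expect_equal(back2$band$lo, W$band$lo)
})
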