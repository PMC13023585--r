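test_that("oscillator_spec enforces its invariants", {
  band <- test_band()
  bad_sym <- diag(3)
  bad_sym[1, 2] <- 0.4
  expect_error(
    oscillator_spec(3, band, duration = 60, coupling = bad_sym),
    "symmetric"
  )
  bad_diag <- matrix(0.5, 3, 3)
  expect_error(
    oscillator_spec(3, band, duration = 60, coupling = bad_diag),
    "diagonal"
  )
  bad_range <- diag(3)
  bad_range[1, 2] <- bad_range[2, 1] <- 1.2
  expect_error(
    oscillator_spec(3, band, duration = 60, coupling = bad_range),
    "\\[0, 1\\]"
  )
  expect_error(
    oscillator_spec(3, band_definition("hi", 100, 140), fs = 256, duration = 60),
    "Nyquist|twice the band"
  )
})

test_that("coupling calibration is monotone, exact at the ends, and rejects sub-floor targets", {
  band <- test_band()
  expect_equal(calibrate_coupling(1, n_segments = 50, band = band), 1)

  w3 <- calibrate_coupling(0.3, n_segments = 50, band = band)
  w6 <- calibrate_coupling(0.6, n_segments = 50, band = band)
  expect_lt(w3, w6)

  fl <- plv_floor(band, n_segments = 50)
  expect_equal(calibrate_coupling(fl, n_segments = 50, band = band), 0)
  expect_error(
    calibrate_coupling(fl / 2, n_segments = 50, band = band),
    "floor"
  )
})

test_that("calibrated targets in [0.2, 0.95] are reproduced within tolerance at 50 segments", {
  band <- test_band()
  curve <- calibration_curve(band, n_segments = 50)
  targets <- c(0.2, 0.45, 0.7, 0.95)
  for (tg in targets) {
    coup <- diag(2)
    coup[1, 2] <- coup[2, 1] <- tg
    spec <- oscillator_spec(2, band,
      duration = 300, coupling = coup,
      seed = 7000 + round(tg * 100)
    )
    W <- connectivity_matrix(simulate_region_signals(spec, curve = curve), band)
    expect_lt(abs(W$values[1, 2] - tg), 0.05)
  }
})

test_that("zero-coupling ensembles measure PLV at the finite-sample floor and perfect coupling at 1", {
  band <- test_band()
  spec0 <- oscillator_spec(4, band, duration = 300, seed = 77)
  W <- connectivity_matrix(simulate_region_signals(spec0), band)
  # Monte-Carlo spread of the zero-coupling expectation, from direct simulation
  fl_samples <- vapply(1:8, function(r) {
    plvnet:::simulate_pair_once(0, band, 256, 50, 6, 9000 + r)
  }, numeric(1))
  mc_se <- sd(fl_samples)
  off <- W$values[upper.tri(W$values)]
  expect_true(all(abs(off - mean(fl_samples)) < 3 * mc_se + 0.02))

  coup <- diag(3)
  coup[1, 2] <- coup[2, 1] <- 1
  spec1 <- oscillator_spec(3, band, duration = 60, coupling = coup, seed = 5)
  W1 <- connectivity_matrix(simulate_region_signals(spec1), band)
  expect_equal(W1$values[1, 2], 1, tolerance = 1e-9)
})

test_that("signal simulation is bit-identical under a fixed seed", {
  band <- test_band()
  coup <- diag(3)
  coup[1, 2] <- coup[2, 1] <- 0.5
  curve <- calibration_curve(band, n_segments = 10)
  spec <- oscillator_spec(3, band, duration = 60, coupling = coup, seed = 12)
  a <- simulate_region_signals(spec, curve = curve)
  b <- simulate_region_signals(spec, curve = curve)
  expect_identical(a$data, b$data)
})

test_that("jointly unrealizable coupling targets fail naming an offending triple", {
  band <- test_band()
  coup <- diag(3)
  coup[1, 2] <- coup[2, 1] <- 0.95
  coup[1, 3] <- coup[3, 1] <- 0.95
  coup[2, 3] <- coup[3, 2] <- 0.2
  spec <- oscillator_spec(3, band, duration = 300, coupling = coup, seed = 2)
  expect_error(
    simulate_region_signals(spec),
    "not jointly realizable.*triple \\(1, 2, 3\\)"
  )
})

test_that("group simulation honours the shape contract and is reproducible", {
  d <- group_design(
    n_subjects = 2, n_regions = 2,
    bands = list(alpha = test_band()),
    base_plv = 0.4, seed = 31
  )
  gd <- simulate_group(d, mode = "matrix")
  expect_length(gd$matrices, 8) # 2 subjects x 2 conditions x 2 times x 1 band
  for (W in gd$matrices) {
    expect_equal(dim(W$values), c(2L, 2L))
    expect_true(isSymmetric(W$values))
  }
  gd2 <- simulate_group(d, mode = "matrix")
  expect_identical(
    lapply(gd$matrices, `[[`, "values"),
    lapply(gd2$matrices, `[[`, "values")
  )

  ds <- group_design(
    n_subjects = 2, n_regions = 3,
    bands = list(alpha = test_band()),
    base_plv = 0.4, duration = 60, seed = 32
  )
  gds <- simulate_group(ds, mode = "signal")
  expect_length(gds$matrices, 8)
  expect_equal(gds$matrices[[1]]$n_segments, 10L)
})

test_that("planted deltas that leave [0, 1] or reference bad regions are rejected", {
  expect_error(
    group_design(
      n_subjects = 4, n_regions = 10, base_plv = 0.9,
      planted_effects = list(planted_effect("without_music", "post", "beta", clique_edges(1:3), 0.25))
    ),
    "outside \\[0, 1\\]"
  )
  expect_error(
    group_design(
      n_subjects = 4, n_regions = 10,
      planted_effects = list(planted_effect("without_music", "post", "beta", clique_edges(9:11), 0.1))
    ),
    "region indices"
  )
  expect_error(
    group_design(
      n_subjects = 4, n_regions = 10,
      planted_effects = list(planted_effect("nope", "post", "beta", clique_edges(1:3), 0.1))
    ),
    "unknown design cell"
  )
})

test_that("null group datasets give uniform edgewise paired-t p-values (KS over 200 reps)", {
  pvals <- unlist(lapply(1:200, function(rep) {
    d <- group_design(
      n_subjects = 34, n_regions = 12,
      bands = list(alpha = test_band()),
      base_plv = 0.3, seed = 40000 + rep
    )
    gd <- simulate_group(d, mode = "matrix")
    res <- edgewise_paired_t(
      get_cell(gd, "alpha", "without_music", "post"),
      get_cell(gd, "alpha", "without_music", "pre")
    )
    res$p[upper.tri(res$p)]
  }))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("group datasets round-trip to CSV with a manifest", {
  d <- group_design(
    n_subjects = 2, n_regions = 4,
    bands = list(alpha = test_band()), seed = 77
  )
  gd <- simulate_group(d, mode = "matrix")
  dir <- tempfile()
  mpath <- write_group_dataset(gd, dir)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  expect_equal(nrow(man$matrices), 8)
  one <- read_plv_matrix(file.path(dir, man$matrices$file[1]))
  expect_equal(one$values, gd$matrices[[man$matrices$key[1]]]$values,
    tolerance = 1e-12
  )
})
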