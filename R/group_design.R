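#' Planted condition-by-time connectivity effect
#'
#' An additive PLV delta on a fixed edge set, applied in exactly one design
#' cell (condition x time) and band. Deltas are added to the target coupling
#' and clipped to `[0, 1]` at generation (clipping is reported).
#'
#' @param condition,time design cell labels
#' @param band band name ("theta", "alpha", "beta")
#' @param edges two-column integer matrix of region index pairs
#' @param delta PLV delta (may be negative)
#' @return object of class `planted_effect`
#' @export
planted_effect <- function(condition, time, band, edges, delta) {
  edges <- matrix(as.integer(edges), ncol = 2)
  stopifnot(nrow(edges) >= 1, all(edges[, 1] != edges[, 2]))
  structure(
    list(
      condition = condition, time = time, band = band,
      edges = edges, delta = delta
    ),
    class = "planted_effect"
  )
}

#' All edges of a clique over the given region indices
#'
#' @param nodes integer vector of region indices (length >= 2)
#' @return two-column matrix of edges
#' @export
clique_edges <- function(nodes) {
  t(utils::combn(as.integer(nodes), 2))
}

#' Crossover group design for surrogate datasets
#'
#' Describes the 2-condition x 2-time within-subject design the generator
#' emulates: per-band baseline coupling, planted cell-specific effects,
#' subject-level coupling heterogeneity, and seeds.
#'
#' @param n_subjects number of subjects (default 34)
#' @param n_regions number of regions (default 78)
#' @param conditions,times ordered factor levels of the crossover design
#' @param bands named list of [band_definition()] (default theta/alpha/beta)
#' @param base_plv baseline off-diagonal target PLV, a single value or a named
#'   vector per band (default 0.30)
#' @param base_coupling optional named list of full target matrices per band,
#'   overriding `base_plv`
#' @param planted_effects list of [planted_effect()] objects
#' @param subject_sd standard deviation of the per-subject coupling jitter
#'   (truncated normal at two standard deviations, default 0.03)
#' @param noise_sd edgewise measurement-noise standard deviation used by the
#'   matrix-mode generator (default 0.02, the scale of segment-averaged PLV
#'   estimation error at 50 segments)
#' @param fs,duration,seg_seconds signal-mode recording parameters (defaults
#'   256 Hz, 300 s, 6 s)
#' @param labels region labels
#' @param seed root seed; all subject/cell substreams derive from it
#' @return object of class `group_design`
#' @export
group_design <- function(n_subjects = 34, n_regions = 78,
                         conditions = c("without_music", "with_music"),
                         times = c("pre", "post"),
                         bands = default_bands(),
                         base_plv = 0.30, base_coupling = NULL,
                         planted_effects = list(),
                         subject_sd = 0.03, noise_sd = 0.02,
                         fs = 256, duration = 300, seg_seconds = 6,
                         labels = NULL, seed = 1L) {
  stopifnot(n_subjects >= 2, n_regions >= 2, length(conditions) == 2, length(times) == 2)
  if (is.null(labels)) labels <- paste0("R", seq_len(n_regions))
  band_names <- names(bands)
  if (is.null(base_coupling)) {
    base_vals <- if (length(base_plv) == 1) {
      stats::setNames(rep(base_plv, length(bands)), band_names)
    } else {
      base_plv[band_names]
    }
    base_coupling <- lapply(band_names, function(b) {
      m <- matrix(base_vals[[b]], n_regions, n_regions)
      diag(m) <- 1
      m
    })
    names(base_coupling) <- band_names
  }
  for (pe in planted_effects) {
    stopifnot(inherits(pe, "planted_effect"))
    if (!pe$condition %in% conditions || !pe$time %in% times || !pe$band %in% band_names) {
      stop_plvnet("group_design: planted effect references an unknown design cell or band")
    }
    if (any(pe$edges < 1 | pe$edges > n_regions)) {
      stop_plvnet("group_design: planted effect references region indices outside 1..n_regions")
    }
    tgt <- base_coupling[[pe$band]][pe$edges] + pe$delta
    if (any(tgt < 0 | tgt > 1)) {
      stop_plvnet("group_design: planted delta pushes target PLV outside [0, 1]")
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
      conditions = conditions, times = times, bands = bands,
      base_coupling = base_coupling, planted_effects = planted_effects,
      subject_sd = subject_sd, noise_sd = noise_sd,
      fs = fs, duration = duration, seg_seconds = seg_seconds,
      labels = as.character(labels), seed = as.integer(seed)
    ),
    class = "group_design"
  )
}

cell_target <- function(design, band_name, condition, time, subject_shift = 0) {
  m <- design$base_coupling[[band_name]]
  for (pe in design$planted_effects) {
    if (pe$band == band_name && pe$condition == condition && pe$time == time) {
      m[pe$edges] <- m[pe$edges] + pe$delta
      m[pe$edges[, 2:1, drop = FALSE]] <- m[pe$edges]
    }
  }
  off <- row(m) != col(m)
  shifted <- m[off] + subject_shift
  n_clip <- sum(shifted < 0 | shifted > 1)
  if (n_clip > 0) {
    message(sprintf(
      "simulate_group: %d target PLV value(s) clipped to [0, 1] in cell (%s, %s, %s)",
      n_clip, condition, time, band_name
    ))
  }
  m[off] <- pmin(pmax(shifted, 0), 1)
  m
}

rtrunc_norm <- function(n, sd, bound = 2 * sd) {
  if (sd == 0) return(rep(0, n))
  x <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(x) > bound)) x[bad] <- stats::rnorm(sum(bad), 0, sd)
  x
}

group_key <- function(subject, condition, time, band) {
  sprintf("s%02d|%s|%s|%s", subject, condition, time, band)
}

#' Simulate a full crossover group dataset
#'
#' Produces one [plv_matrix()] per subject x condition x time x band. Two
#' generation modes:
#'
#' * `"signal"` — every matrix is measured by running
#'   [simulate_region_signals()] output through the real
#'   [connectivity_matrix()] pipeline (band-pass, 6-s segments, analytic-signal
#'   phases, segment-averaged PLV). Faithful but costly; meant for moderate
#'   sizes.
#' * `"matrix"` — PLV-scale sampling: target + per-subject coupling shift +
#'   edgewise Gaussian measurement noise (`noise_sd`), clipped to `[0, 1]`.
#'   Statistically matched to the signal mode at its default noise scale and
#'   fast enough for the 200-repetition calibration studies.
#'
#' Per-subject coupling heterogeneity is a truncated-normal shift shared
#' across the four cells of that subject (a subject random effect), so paired
#' contrasts cancel it. Fully reproducible from the design's root seed.
#'
#' @param design a [group_design()]
#' @param mode `"matrix"` or `"signal"`
#' @return object of class `group_dataset`: `matrices` (named list of
#'   [plv_matrix()]), `index` (data.frame of subject/condition/time/band/key),
#'   `design`, `mode`
#' @export
simulate_group <- function(design, mode = c("matrix", "signal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "group_design"))
  band_names <- names(design$bands)
  n_segments <- floor(design$duration / design$seg_seconds)
  cells <- expand.grid(
    time = design$times, condition = design$conditions,
    stringsAsFactors = FALSE
  )[, c("condition", "time")]

  seeds <- derive_seeds(design$seed, 1L + design$n_subjects * nrow(cells) * length(band_names))
  subj_shift_seed <- seeds[1]
  cell_seeds <- array(seeds[-1],
    dim = c(design$n_subjects, nrow(cells), length(band_names))
  )
  subj_shift <- with_seed(
    subj_shift_seed,
    matrix(rtrunc_norm(design$n_subjects * length(band_names), design$subject_sd),
      nrow = design$n_subjects,
      dimnames = list(NULL, band_names)
    )
  )

  curves <- NULL
  if (mode == "signal") {
    curves <- lapply(design$bands, function(b) {
      calibration_curve(b,
        fs = design$fs, seg_seconds = design$seg_seconds,
        n_segments = n_segments
      )
    })
  }

  matrices <- list()
  idx <- list()
  for (bi in seq_along(band_names)) {
    bname <- band_names[bi]
    band <- design$bands[[bname]]
    for (ci in seq_len(nrow(cells))) {
      cond <- cells$condition[ci]
      tm <- cells$time[ci]
      for (s in seq_len(design$n_subjects)) {
        target <- cell_target(design, bname, cond, tm, subj_shift[s, bname])
        seed_sc <- cell_seeds[s, ci, bi]
        if (mode == "signal") {
          spec <- oscillator_spec(
            n_regions = design$n_regions, band = band, fs = design$fs,
            duration = design$duration, coupling = target, seed = seed_sc,
            labels = design$labels
          )
          W <- connectivity_matrix(
            simulate_region_signals(spec, curve = curves[[bname]],
              seg_seconds = design$seg_seconds
            ),
            band, design$seg_seconds
          )
        } else {
          n <- design$n_regions
          noise <- with_seed(seed_sc, {
            e <- matrix(0, n, n)
            e[upper.tri(e)] <- stats::rnorm(n * (n - 1) / 2, 0, design$noise_sd)
            e + t(e)
          })
          vals <- pmin(pmax(target + noise, 0), 1)
          diag(vals) <- 1
          W <- plv_matrix(vals,
            labels = design$labels, band = band,
            n_segments = n_segments
          )
        }
        key <- group_key(s, cond, tm, bname)
        matrices[[key]] <- W
        idx[[length(idx) + 1L]] <- data.frame(
          subject = s, condition = cond, time = tm, band = bname, key = key,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(
    list(
      matrices = matrices, index = do.call(rbind, idx),
      design = design, mode = mode
    ),
    class = "group_dataset"
  )
}

#' @export
print.group_dataset <- function(x, ...) {
  cat(sprintf(
    "<group_dataset> %d matrices (%d subjects x %d conditions x %d times x %d bands), mode \"%s\"\n",
    length(x$matrices), x$design$n_subjects, length(x$design$conditions),
    length(x$design$times), length(x$design$bands), x$mode
  ))
  invisible(x)
}

#' Extract one design cell as a subject-ordered list of PLV matrices
#'
#' @param gd a `group_dataset`
#' @param band,condition,time cell selectors
#' @return list of [plv_matrix()] ordered by subject
#' @export
get_cell <- function(gd, band, condition, time) {
  keys <- group_key(seq_len(gd$design$n_subjects), condition, time, band)
  missing <- setdiff(keys, names(gd$matrices))
  if (length(missing)) stop_plvnet("get_cell: unknown design cell requested")
  gd$matrices[keys]
}

#' Write a group dataset as per-matrix CSV files plus a manifest
#'
#' @param gd a `group_dataset`
#' @param dir output directory (created if needed)
#' @return the manifest path, invisibly
#' @export
write_group_dataset <- function(gd, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(nrow(gd$index))
  for (i in seq_len(nrow(gd$index))) {
    key <- gd$index$key[i]
    f <- file.path(dir, paste0(gsub("[|]", "_", key), ".csv"))
    write_plv_matrix(gd$matrices[[key]], f)
    files[i] <- basename(f)
  }
  manifest <- cbind(gd$index, file = files)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(
      seed = gd$design$seed, mode = gd$mode,
      n_subjects = gd$design$n_subjects, matrices = manifest
    ),
    mpath,
    auto_unbox = TRUE, digits = NA
  )
  invisible(mpath)
}
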