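#' Pipeline run configuration
#'
#' One object holding every stage's parameters, with the study's standard
#' defaults: theta/alpha/beta bands, 6-s segments, sparsity 0.06-0.50 step
#' 0.02, 1000 random networks per level, NBS edge p 0.001 / component p 0.05 /
#' 2000 permutations, 34 subjects, 256 Hz, 300 s. Every default is
#' overridable and every override lands in the run manifest. The object
#' round-trips through JSON serialization unchanged.
#'
#' @param n_subjects,n_regions design size (defaults 34, 78)
#' @param bands named list of [band_definition()]
#' @param seg_seconds segment length (default 6)
#' @param sparsity_start,sparsity_stop,sparsity_step sparsity grid (defaults
#'   0.06, 0.50, 0.02)
#' @param n_random random networks per sparsity level (default 1000)
#' @param nbs_edge_alpha,nbs_component_alpha,nbs_n_perm NBS parameters
#'   (defaults 0.001, 0.05, 2000)
#' @param base_plv baseline coupling target (default 0.30)
#' @param planted_effects list of [planted_effect()]
#' @param subject_sd,noise_sd generator heterogeneity/noise (defaults 0.03,
#'   0.02)
#' @param fs,duration recording parameters (defaults 256 Hz, 300 s)
#' @param mode `"matrix"` or `"signal"` generation (default `"matrix"`)
#' @param partition_path region-to-network TSV; default the shipped synthetic
#'   78-region partition
#' @param out_dir output directory
#' @param seed root seed for the whole run
#' @return object of class `run_config`
#' @export
run_config <- function(n_subjects = 34, n_regions = 78,
                       bands = default_bands(), seg_seconds = 6,
                       sparsity_start = 0.06, sparsity_stop = 0.50,
                       sparsity_step = 0.02, n_random = 1000,
                       nbs_edge_alpha = 0.001, nbs_component_alpha = 0.05,
                       nbs_n_perm = 2000,
                       base_plv = 0.30, planted_effects = list(),
                       subject_sd = 0.03, noise_sd = 0.02,
                       fs = 256, duration = 300,
                       mode = c("matrix", "signal"),
                       partition_path = NULL, out_dir = tempfile("plvnet_run_"),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(partition_path)) {
    partition_path <- system.file("extdata", "partition_78_synthetic.tsv",
      package = "plvnet"
    )
  }
  cfg <- list(
    n_subjects = n_subjects, n_regions = n_regions,
    bands = lapply(bands, unclass), seg_seconds = seg_seconds,
    sparsity_start = sparsity_start, sparsity_stop = sparsity_stop,
    sparsity_step = sparsity_step, n_random = n_random,
    nbs_edge_alpha = nbs_edge_alpha, nbs_component_alpha = nbs_component_alpha,
    nbs_n_perm = nbs_n_perm,
    base_plv = base_plv,
    planted_effects = lapply(planted_effects, function(pe) {
      list(
        condition = pe$condition, time = pe$time, band = pe$band,
        edges = pe$edges, delta = pe$delta
      )
    }),
    subject_sd = subject_sd, noise_sd = noise_sd,
    fs = fs, duration = duration, mode = mode,
    partition_path = partition_path, out_dir = out_dir,
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as JSON
#' @param cfg a [run_config()]
#' @param path JSON path
#' @return the config (read) or `path` (write, invisibly)
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw$bands)) {
    bands <- lapply(seq_len(nrow(raw$bands)), function(i) {
      band_definition(raw$bands$name[i], raw$bands$lo[i], raw$bands$hi[i])
    })
    names(bands) <- raw$bands$name
  } else {
    bands <- lapply(raw$bands, function(b) band_definition(b$name, b$lo, b$hi))
  }
  pes <- list()
  if (length(raw$planted_effects)) {
    pes <- lapply(seq_along(raw$planted_effects$condition), function(i) {
      planted_effect(
        raw$planted_effects$condition[i], raw$planted_effects$time[i],
        raw$planted_effects$band[i],
        matrix(raw$planted_effects$edges[[i]], ncol = 2),
        raw$planted_effects$delta[i]
      )
    })
  }
  run_config(
    n_subjects = raw$n_subjects, n_regions = raw$n_regions,
    bands = bands, seg_seconds = raw$seg_seconds,
    sparsity_start = raw$sparsity_start, sparsity_stop = raw$sparsity_stop,
    sparsity_step = raw$sparsity_step, n_random = raw$n_random,
    nbs_edge_alpha = raw$nbs_edge_alpha,
    nbs_component_alpha = raw$nbs_component_alpha,
    nbs_n_perm = raw$nbs_n_perm, base_plv = raw$base_plv,
    planted_effects = pes, subject_sd = raw$subject_sd,
    noise_sd = raw$noise_sd, fs = raw$fs, duration = raw$duration,
    mode = raw$mode, partition_path = raw$partition_path,
    out_dir = raw$out_dir, seed = raw$seed
  )
}

design_from_config <- function(cfg, labels) {
  bands <- lapply(cfg$bands, function(b) band_definition(b$name, b$lo, b$hi))
  names(bands) <- vapply(bands, `[[`, character(1), "name")
  group_design(
    n_subjects = cfg$n_subjects, n_regions = cfg$n_regions,
    bands = bands, base_plv = cfg$base_plv,
    planted_effects = lapply(cfg$planted_effects, function(pe) {
      planted_effect(pe$condition, pe$time, pe$band, pe$edges, pe$delta)
    }),
    subject_sd = cfg$subject_sd, noise_sd = cfg$noise_sd,
    fs = cfg$fs, duration = cfg$duration, seg_seconds = cfg$seg_seconds,
    labels = labels, seed = cfg$seed
  )
}

pipeline_log <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full study-replica pipeline
#'
#' simulate -> connectivity -> graph metrics -> NBS contrasts -> network
#' strengths -> inferential statistics, from a single [run_config()]. Every
#' intermediate artifact is written under `cfg$out_dir` and listed, with an
#' MD5 content hash, in `manifest.json`; re-running the same config reproduces
#' identical hashes.
#'
#' Contrasts computed per band: post vs pre within each condition, and
#' with-music vs without-music at each time (NBS + paired t on total average
#' PLV); 2 x 2 RM-ANOVA per aggregated graph metric; Friedman + Dunn across
#' the four design cells for every strength measure.
#'
#' @param cfg a [run_config()]
#' @param quiet suppress per-stage log lines (default FALSE)
#' @return the manifest, invisibly (list with `artifacts` data.frame)
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  add_artifact <- function(p) artifacts <<- c(artifacts, p)

  stage <- "partition"
  partition <- tryCatch(
    validate_partition(cfg$partition_path),
    error = function(e) stop_plvnet(sprintf("stage %s failed: %s", stage, conditionMessage(e)))
  )
  labels <- names(partition)
  if (length(labels) != cfg$n_regions) {
    labels <- labels[seq_len(min(cfg$n_regions, length(labels)))]
    if (length(labels) < cfg$n_regions) {
      stop_plvnet(sprintf(
        "stage partition failed: partition has %d regions, config wants %d",
        length(labels), cfg$n_regions
      ))
    }
  }
  pipeline_log(
    quiet, stage, "%d regions over networks: %s", length(labels),
    paste(sprintf("%s=%d", names(table(partition[labels])), table(partition[labels])), collapse = " ")
  )

  stage <- "simulate"
  gd <- design_from_config(cfg, labels)
  gd <- simulate_group(gd, mode = cfg$mode)
  mdir <- file.path(out, "connectivity")
  write_group_dataset(gd, mdir)
  add_artifact(list.files(mdir, full.names = TRUE))
  pipeline_log(quiet, stage, "%d PLV matrices (mode %s)", length(gd$matrices), cfg$mode)

  stage <- "graph"
  grid <- sparsity_grid(cfg$sparsity_start, cfg$sparsity_stop, cfg$sparsity_step)
  prof_seeds <- derive_seeds(cfg$seed + 7L, nrow(gd$index))
  metric_rows <- lapply(seq_len(nrow(gd$index)), function(i) {
    mp <- metric_profile(gd$matrices[[gd$index$key[i]]],
      grid = grid,
      n_random = cfg$n_random, seed = prof_seeds[i]
    )
    cbind(gd$index[i, c("subject", "condition", "time", "band")],
      as.data.frame(t(mp$aggregate)),
      row.names = NULL
    )
  })
  metrics <- do.call(rbind, metric_rows)
  mfile <- file.path(out, "metrics.csv")
  utils::write.csv(metrics, mfile, row.names = FALSE)
  add_artifact(mfile)
  pipeline_log(
    quiet, stage, "%d metric profiles (%d levels x %d nulls)",
    nrow(metrics), length(grid$levels), cfg$n_random
  )

  stage <- "anova"
  anova_rows <- list()
  for (b in names(cfg$bands)) {
    for (m in c("cp", "lp", "eglob", "eloc", "gamma", "lambda", "sigma")) {
      sub <- metrics[metrics$band == b, ]
      tab <- data.frame(
        subject = sub$subject, condition = sub$condition,
        time = sub$time, value = sub[[m]]
      )
      res <- rm_anova_2x2(tab)
      res$band <- b
      res$metric <- m
      anova_rows[[length(anova_rows) + 1L]] <- res
    }
  }
  anova_tab <- do.call(rbind, anova_rows)
  afile <- file.path(out, "anova_metrics.csv")
  utils::write.csv(anova_tab, afile, row.names = FALSE)
  add_artifact(afile)
  pipeline_log(quiet, stage, "%d RM-ANOVA effects", nrow(anova_tab))

  stage <- "nbs"
  ncfg_base <- nbs_config(
    edge_alpha = cfg$nbs_edge_alpha,
    component_alpha = cfg$nbs_component_alpha,
    n_perm = cfg$nbs_n_perm, seed = cfg$seed + 13L
  )
  contrasts <- list()
  for (cond in gd$design$conditions) {
    contrasts[[paste0(cond, "_post_vs_pre")]] <- local({
      cond_fixed <- cond
      list(
        a = function(b) get_cell(gd, b, cond_fixed, "post"),
        b = function(b) get_cell(gd, b, cond_fixed, "pre")
      )
    })
  }
  for (tm in gd$design$times) {
    contrasts[[paste0("with_vs_without_music_", tm)]] <- local({
      tm_fixed <- tm
      list(
        a = function(b) get_cell(gd, b, gd$design$conditions[2], tm_fixed),
        b = function(b) get_cell(gd, b, gd$design$conditions[1], tm_fixed)
      )
    })
  }
  nbs_summary <- list()
  ndir <- file.path(out, "nbs")
  dir.create(ndir, showWarnings = FALSE)
  for (cname in names(contrasts)) {
    for (b in names(cfg$bands)) {
      a_m <- contrasts[[cname]]$a(b)
      b_m <- contrasts[[cname]]$b(b)
      res <- nbs_test(a_m, b_m, ncfg_base)
      f <- file.path(ndir, sprintf("nbs_%s_%s.json", cname, b))
      write_nbs_result(res, f)
      add_artifact(c(f, paste0(f, ".edges.tsv")))
      sig <- nbs_significant(res)
      tap_a <- vapply(a_m, total_average_plv, numeric(1))
      tap_b <- vapply(b_m, total_average_plv, numeric(1))
      tt <- tryCatch(paired_t(tap_a, tap_b), error = function(e) list(t = NA, p.value = NA))
      nbs_summary[[length(nbs_summary) + 1L]] <- data.frame(
        contrast = cname, band = b,
        n_components = length(res$components),
        n_significant = length(sig),
        largest_significant = if (length(sig)) max(vapply(sig, `[[`, numeric(1), "size")) else 0,
        total_plv_t = tt$t, total_plv_p = tt$p.value
      )
    }
  }
  nbs_tab <- do.call(rbind, nbs_summary)
  nfile <- file.path(out, "nbs_summary.csv")
  utils::write.csv(nbs_tab, nfile, row.names = FALSE)
  add_artifact(nfile)
  pipeline_log(quiet, stage, "%d contrasts x bands tested", nrow(nbs_tab))

  stage <- "strength"
  st <- strength_table(gd, partition)
  sfile <- file.path(out, "strengths.csv")
  utils::write.csv(st, sfile, row.names = FALSE)
  add_artifact(sfile)

  stage <- "stats"
  fried_rows <- list()
  for (b in unique(st$band)) {
    for (m in unique(st$measure)) {
      sub <- st[st$band == b & st$measure == m, ]
      cell <- interaction(sub$condition, sub$time)
      blocks <- do.call(cbind, lapply(levels(cell), function(cl) {
        sub$value[cell == cl][order(sub$subject[cell == cl])]
      }))
      colnames(blocks) <- levels(cell)
      fr <- tryCatch(friedman_test(blocks), error = function(e) NULL)
      if (is.null(fr)) next
      dn <- dunn_posthoc(blocks)
      fried_rows[[length(fried_rows) + 1L]] <- data.frame(
        band = b, measure = m, chi2 = fr$statistic, df = fr$df,
        p = fr$p.value, min_dunn_p_adj = min(dn$p_adj)
      )
    }
  }
  fried_tab <- do.call(rbind, fried_rows)
  ffile <- file.path(out, "friedman_strengths.csv")
  utils::write.csv(fried_tab, ffile, row.names = FALSE)
  add_artifact(ffile)
  pipeline_log(quiet, stage, "%d Friedman omnibus tests", nrow(fried_tab))

  stage <- "manifest"
  files <- unlist(artifacts)
  hashes <- tools::md5sum(files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("plvnet")),
    seed = cfg$seed,
    config = unclass(cfg),
    artifacts = data.frame(
      file = sub(paste0("^", gsub("([.*+?^${}()|\\[\\]\\\\])", "\\\\\\1", out), "/?"), "", files),
      md5 = unname(hashes)
    ),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  pipeline_log(quiet, stage, "%d artifacts hashed", nrow(manifest$artifacts))
  invisible(manifest)
}
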