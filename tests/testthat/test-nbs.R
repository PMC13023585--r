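make_paired_sets <- function(n_subjects, n_regions, seed, delta_edge = NULL, delta = 0) {
  set.seed(seed)
  make_one <- function(shift_edge = FALSE) {
    m <- matrix(0, n_regions, n_regions)
    m[upper.tri(m)] <- pmin(pmax(0.3 + rnorm(n_regions * (n_regions - 1) / 2, 0, 0.05), 0), 1)
    m <- m + t(m)
    if (shift_edge && !is.null(delta_edge)) {
      m[delta_edge[1], delta_edge[2]] <- m[delta_edge[1], delta_edge[2]] + delta
      m[delta_edge[2], delta_edge[1]] <- m[delta_edge[1], delta_edge[2]]
    }
    diag(m) <- 1
    plv_matrix(pmin(m, 1))
  }
  list(
    a = lapply(seq_len(n_subjects), function(s) make_one(TRUE)),
    b = lapply(seq_len(n_subjects), function(s) make_one(FALSE))
  )
}

test_that("identical paired inputs give t = 0 everywhere", {
  sets <- make_paired_sets(5, 6, seed = 1)
  res <- edgewise_paired_t(sets$a, sets$a)
  ut <- upper.tri(res$t)
  expect_true(all(res$t[ut] == 0))
  expect_true(all(res$p[ut] == 1))
  expect_false(any(res$flagged))
})

test_that("a constant planted edge difference reproduces the hand-computed paired t", {
  n <- 8
  sets <- make_paired_sets(n, 5, seed = 2, delta_edge = c(1, 2), delta = 0.1)
  res <- edgewise_paired_t(sets$a, sets$b)
  # direct formula oracle on the printed difference vector
  d <- vapply(seq_len(n), function(s) {
    sets$a[[s]]$values[1, 2] - sets$b[[s]]$values[1, 2]
  }, numeric(1))
  t_oracle <- mean(d) / (sd(d) / sqrt(n))
  expect_equal(res$t[1, 2], t_oracle, tolerance = 1e-12)
  expect_equal(res$t[2, 1], t_oracle, tolerance = 1e-12)
  expect_equal(res$df, n - 1)
})

test_that("constant non-zero differences are flagged and excluded", {
  sets <- make_paired_sets(5, 4, seed = 3)
  b_shift <- lapply(sets$a, function(W) {
    v <- W$values
    v[1, 2] <- v[2, 1] <- v[1, 2] - 0.05 # identical shift for every subject
    plv_matrix(v)
  })
  res <- edgewise_paired_t(sets$a, b_shift)
  expect_true(res$flagged[1, 2])
  expect_true(is.na(res$t[1, 2]))
  res_nbs <- nbs_test(sets$a, b_shift, nbs_config(n_perm = 100, seed = 1))
  expect_equal(res_nbs$n_flagged, 1L)
})

test_that("edgewise false-positive rate is near nominal on null data", {
  fracs <- vapply(1:60, function(rep) {
    d <- group_design(
      n_subjects = 12, n_regions = 15,
      bands = list(alpha = test_band()), seed = 50000 + rep
    )
    gd <- simulate_group(d, mode = "matrix")
    res <- edgewise_paired_t(
      get_cell(gd, "alpha", "with_music", "post"),
      get_cell(gd, "alpha", "with_music", "pre")
    )
    mean(res$p[upper.tri(res$p)] < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("component finding matches the igraph oracle on random suprathreshold graphs", {
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(6:20, 1)
    k <- sample(1:15, 1)
    pairs <- t(combn(n, 2))
    sel <- pairs[sample(nrow(pairs), min(k, nrow(pairs))), , drop = FALSE]
    memb <- plvnet:::component_membership(sel[, 1], sel[, 2])
    maxsz <- plvnet:::max_component_edges(sel[, 1], sel[, 2])

    ig <- igraph::graph_from_edgelist(sel, directed = FALSE)
    comp <- igraph::components(ig)
    edge_comp <- comp$membership[sel[, 1]]
    # same partition of edges into components
    expect_equal(length(unique(memb)), sum(table(edge_comp) > 0))
    expect_identical(
      as.integer(sort(table(memb))),
      as.integer(sort(table(edge_comp)))
    )
    expect_equal(maxsz, max(table(edge_comp)))
  }
})

test_that("nbs_test enumerates all sign flips when 2^n <= n_perm and the exact p matches a brute-force oracle", {
  n <- 8
  sets <- make_paired_sets(n, 6, seed = 4, delta_edge = c(1, 2), delta = 0.25)
  cfg <- nbs_config(edge_alpha = 0.01, n_perm = 300, seed = 5)
  res <- nbs_test(sets$a, sets$b, cfg)
  expect_true(res$exact)
  expect_length(res$null_max_sizes, 2^n)
  expect_gte(length(res$components), 1)

  # brute-force oracle: loop over all sign patterns with per-edge t.test
  D <- plvnet:::stack_upper(sets$a) - plvnet:::stack_upper(sets$b)
  t_crit <- qt(1 - cfg$edge_alpha / 2, n - 1)
  pairs <- which(upper.tri(diag(6)), arr.ind = TRUE)
  null_sizes <- apply(as.matrix(expand.grid(rep(list(c(-1, 1)), n))), 1, function(s) {
    tt <- apply(D * s, 2, function(col) {
      if (sd(col) == 0) return(0)
      t.test(col)$statistic
    })
    max(
      plvnet:::max_component_edges(pairs[tt > t_crit, 1], pairs[tt > t_crit, 2]),
      plvnet:::max_component_edges(pairs[tt < -t_crit, 1], pairs[tt < -t_crit, 2])
    )
  })
  obs_size <- res$components[[1]]$size
  expect_equal(res$components[[1]]$p_corrected, mean(null_sizes >= obs_size))
  expect_identical(sort(res$null_max_sizes), sort(as.numeric(null_sizes)))
})

test_that("nbs results are deterministic under a fixed seed and empty when nothing is suprathreshold", {
  sets <- make_paired_sets(20, 10, seed = 6)
  cfg <- nbs_config(n_perm = 200, seed = 9)
  r1 <- nbs_test(sets$a, sets$b, cfg)
  r2 <- nbs_test(sets$a, sets$b, cfg)
  expect_identical(r1$null_max_sizes, r2$null_max_sizes)

  # force an empty result: identical groups have t = 0 everywhere
  r_empty <- nbs_test(sets$a, sets$a, cfg)
  expect_length(r_empty$components, 0)
  expect_equal(sum(r_empty$suprathreshold), 0)
})

test_that("corrected p-values lie in (0, 1] and shrink with component size for a fixed null", {
  sets <- make_paired_sets(15, 8, seed = 7, delta_edge = c(1, 2), delta = 0.3)
  res <- nbs_test(sets$a, sets$b, nbs_config(edge_alpha = 0.05, component_alpha = 0.25, n_perm = 200, seed = 2))
  for (co in res$components) {
    expect_gt(co$p_corrected, 0)
    expect_lte(co$p_corrected, 1)
  }
  null <- res$null_max_sizes
  p_for_size <- vapply(1:10, function(sz) (1 + sum(null >= sz)) / (1 + length(null)), numeric(1))
  expect_true(all(diff(p_for_size) <= 0))
})

test_that("planted clique effects are recovered as significant components", {
  d <- group_design(
    n_subjects = 34, n_regions = 30,
    bands = list(beta = default_bands()$beta),
    planted_effects = list(
      planted_effect("without_music", "post", "beta", clique_edges(1:6), 0.25)
    ),
    seed = 99
  )
  gd <- simulate_group(d, mode = "matrix")
  res <- nbs_test(
    get_cell(gd, "beta", "without_music", "post"),
    get_cell(gd, "beta", "without_music", "pre"),
    nbs_config(n_perm = 500, seed = 4)
  )
  sig <- nbs_significant(res)
  expect_gte(length(sig), 1)
  planted <- clique_edges(1:6)
  planted_keys <- paste(planted[, 1], planted[, 2])
  found_keys <- unlist(lapply(sig, function(co) {
    paste(co$edge_index[, 1], co$edge_index[, 2])
  }))
  coverage <- mean(planted_keys %in% found_keys)
  expect_gte(coverage, 0.8)
})

test_that("nbs results serialize to JSON and edge TSV", {
  sets <- make_paired_sets(10, 6, seed = 8, delta_edge = c(2, 3), delta = 0.3)
  res <- nbs_test(sets$a, sets$b, nbs_config(edge_alpha = 0.05, component_alpha = 0.25, n_perm = 150, seed = 3))
  f <- tempfile(fileext = ".json")
  write_nbs_result(res, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(length(back$null_max_sizes), length(res$null_max_sizes))
  tsv <- utils::read.delim(paste0(f, ".edges.tsv"))
  expect_true(all(c("component", "region_a", "region_b", "sign", "p_corrected") %in% names(tsv)))
})
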