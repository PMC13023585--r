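provenance_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version-pinned serialization so the hash is stable across sessions
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Two-by-two repeated-measures ANOVA with partial eta squared
#'
#' Fully within-subject 2 x 2 design (factor A: condition, factor B: time).
#' Sums of squares are decomposed with subject-by-effect error strata: each
#' effect is tested against its own subject interaction
#' (`F = MS_effect / MS_{effect x subject}`, df (1, n - 1)), and partial eta
#' squared is `SS_effect / (SS_effect + SS_error_effect)`. Sphericity is not
#' an issue for 1-df within effects, so no correction is applied.
#'
#' @param table long data.frame with columns for subject, the two factors and
#'   the response; every subject must have all four cells exactly once
#' @param subject,a,b,value column names (defaults `subject`, `condition`,
#'   `time`, `value`)
#' @return data.frame with one row per effect (`A`, `B`, `A:B`): `F`, `df1`,
#'   `df2`, `p`, `peta2`, and the SS columns; attribute `input_hash` records a
#'   digest of the input table
#' @export
rm_anova_2x2 <- function(table, subject = "subject", a = "condition",
                         b = "time", value = "value") {
  df <- data.frame(
    s = factor(table[[subject]]), A = factor(table[[a]]),
    B = factor(table[[b]]), y = as.numeric(table[[value]])
  )
  if (nlevels(df$A) != 2 || nlevels(df$B) != 2) {
    stop_plvnet("rm_anova_2x2: both factors must have exactly 2 levels")
  }
  if (any(is.na(df$y))) stop_plvnet("rm_anova_2x2: missing response values")
  n <- nlevels(df$s)
  if (n < 3) stop_plvnet("rm_anova_2x2: need at least 3 subjects")
  counts <- table(df$s, df$A, df$B)
  if (any(counts != 1)) {
    miss <- which(counts == 0, arr.ind = TRUE)
    cells <- apply(miss, 1, function(r) {
      sprintf(
        "(%s, %s, %s)", dimnames(counts)[[1]][r[1]],
        dimnames(counts)[[2]][r[2]], dimnames(counts)[[3]][r[3]]
      )
    })
    stop_plvnet(sprintf(
      "rm_anova_2x2: design incomplete; missing/duplicated cells: %s",
      paste(cells, collapse = ", ")
    ))
  }

  M <- mean(df$y)
  m_a <- tapply(df$y, df$A, mean)
  m_b <- tapply(df$y, df$B, mean)
  m_s <- tapply(df$y, df$s, mean)
  m_ab <- tapply(df$y, list(df$A, df$B), mean)
  m_as <- tapply(df$y, list(df$A, df$s), mean)
  m_bs <- tapply(df$y, list(df$B, df$s), mean)

  ss_a <- 2 * n * sum((m_a - M)^2)
  ss_b <- 2 * n * sum((m_b - M)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, 2)) - outer(rep(1, 2), m_b) + M)^2)
  ss_s <- 4 * sum((m_s - M)^2)
  ss_as <- 2 * sum((m_as - outer(m_a, rep(1, n)) - outer(rep(1, 2), m_s) + M)^2)
  ss_bs <- 2 * sum((m_bs - outer(m_b, rep(1, n)) - outer(rep(1, 2), m_s) + M)^2)
  ss_tot <- sum((df$y - M)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs
  ss_abs <- max(ss_abs, 0)

  eff <- function(name, ss_e, ss_err) {
    df1 <- 1
    df2 <- n - 1
    f <- if (ss_err > 0) (ss_e / df1) / (ss_err / df2) else ifelse(ss_e > 0, Inf, 0)
    data.frame(
      effect = name, F = f, df1 = df1, df2 = df2,
      p = stats::pf(f, df1, df2, lower.tail = FALSE),
      peta2 = if (ss_e + ss_err > 0) ss_e / (ss_e + ss_err) else 0,
      ss_effect = ss_e, ss_error = ss_err
    )
  }
  out <- rbind(
    eff("A", ss_a, ss_as),
    eff("B", ss_b, ss_bs),
    eff("A:B", ss_ab, ss_abs)
  )
  attr(out, "ss_total") <- ss_tot
  attr(out, "ss_subject") <- ss_s
  attr(out, "input_hash") <- provenance_hash(df)
  out
}

row_midranks <- function(blocks) {
  t(apply(blocks, 1, rank)) # rank() uses midranks for ties
}

friedman_chi2 <- function(r) {
  n <- nrow(r)
  k <- ncol(r)
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  if (A - C <= 0) return(NA_real_) # every row constant: statistic degenerate
  (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
}

#' Friedman rank test for k related samples
#'
#' Tie-corrected statistic
#' `chi2 = (k - 1) * sum_j (R_j - n(k+1)/2)^2 / (A - C)` with midranks
#' (`A = sum of squared ranks`, `C = n k (k+1)^2 / 4`), which reduces to the
#' textbook `12/(nk(k+1)) sum R_j^2 - 3n(k+1)` without ties. The p-value comes
#' from the chi-squared reference distribution with `k - 1` df; with
#' `exact = TRUE` the full within-row permutation distribution is enumerated
#' (feasible while `(k!)^n <= 250000`).
#'
#' @param blocks numeric matrix, subjects in rows, k >= 3 conditions in columns
#' @param exact enumerate the exact permutation distribution (default FALSE)
#' @return list `(statistic, df, p.value, method)`; with `exact`, `p.exact`
#' @export
friedman_test <- function(blocks, exact = FALSE) {
  blocks <- as.matrix(blocks)
  n <- nrow(blocks)
  k <- ncol(blocks)
  stopifnot(k >= 3, n >= 2)
  r <- row_midranks(blocks)
  stat <- friedman_chi2(r)
  if (is.na(stat)) {
    stop_plvnet("friedman_test: all rows constant; statistic degenerate")
  }
  out <- list(
    statistic = stat, df = k - 1,
    p.value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
    method = "Friedman rank sum test (tie-corrected)",
    input_hash = provenance_hash(blocks)
  )
  if (exact) {
    n_combos <- factorial(k)^n
    if (n_combos > 250000) {
      stop_plvnet(sprintf(
        "friedman_test: exact enumeration needs (k!)^n = %.3g combinations (cap 250000)",
        n_combos
      ))
    }
    perms <- perm_matrix(k)
    np <- nrow(perms)
    idx <- rep(1L, n)
    stats_all <- numeric(n_combos)
    rp <- r
    for (c in seq_len(n_combos)) {
      for (s in seq_len(n)) rp[s, ] <- r[s, perms[idx[s], ]]
      stats_all[c] <- friedman_chi2(rp)
      # odometer increment over per-subject permutation indices
      s <- 1L
      while (s <= n) {
        idx[s] <- idx[s] + 1L
        if (idx[s] <= np) break
        idx[s] <- 1L
        s <- s + 1L
      }
    }
    out$p.exact <- mean(stats_all >= stat - 1e-12)
  }
  out
}

perm_matrix <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(k - 1)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    left <- sub[, seq_len(pos - 1), drop = FALSE]
    right <- if (pos <= k - 1) sub[, pos:(k - 1), drop = FALSE] else sub[, 0, drop = FALSE]
    cbind(left, k, right, deparse.level = 0)
  }))
}

#' Dunn's post hoc test after Friedman
#'
#' For each of the `k(k-1)/2` condition pairs, a z statistic from the
#' mean-rank difference with standard error `sqrt(k(k+1)/(6n))`, a two-sided
#' normal p-value, and a Bonferroni-adjusted p
#' (`min(1, p * number_of_pairs)`).
#'
#' @param blocks numeric matrix, subjects in rows, conditions in columns
#' @return data.frame: `cond_a`, `cond_b`, `z`, `p_raw`, `p_adj`
#' @export
dunn_posthoc <- function(blocks) {
  blocks <- as.matrix(blocks)
  n <- nrow(blocks)
  k <- ncol(blocks)
  stopifnot(k >= 3, n >= 2)
  cn <- colnames(blocks)
  if (is.null(cn)) cn <- paste0("C", seq_len(k))
  r <- row_midranks(blocks)
  mean_ranks <- colMeans(r)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  z <- (mean_ranks[pairs[1, ]] - mean_ranks[pairs[2, ]]) / se
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(
    cond_a = cn[pairs[1, ]], cond_b = cn[pairs[2, ]],
    z = unname(z), p_raw = unname(p_raw),
    p_adj = pmin(1, unname(p_raw) * n_pairs),
    row.names = NULL
  )
}

#' Paired t-test
#'
#' Standard paired t on the differences `a - b`, `df = n - 1`, two-sided p.
#'
#' @param a,b numeric vectors of equal length >= 3
#' @return list `(t, df, p.value, mean_diff)`
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- a - b
  if (stats::var(d) == 0) {
    if (all(d == 0)) {
      # identical samples carry no evidence against the null
      return(list(t = 0, df = length(d) - 1, p.value = 1, mean_diff = 0))
    }
    stop_plvnet("paired_t: zero variance of non-zero paired differences; t undefined")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p.value = ht$p.value, mean_diff = unname(ht$estimate)
  )
}
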