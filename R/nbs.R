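#' Network-Based Statistic configuration
#'
#' Defaults follow the standard paired-connectome correction setup: edge
#' p < 0.001, component p < 0.05, 2000 permutations.
#'
#' @param edge_alpha edgewise threshold p-value (default 0.001)
#' @param component_alpha corrected component-level alpha (default 0.05)
#' @param n_perm number of sign-flip permutations (default 2000, minimum 100)
#' @param seed integer seed for the permutation stream
#' @param tail `"two_sided"` (components formed separately per sign),
#'   `"greater"`, or `"less"`
#' @return object of class `nbs_config`
#' @export
nbs_config <- function(edge_alpha = 0.001, component_alpha = 0.05,
                       n_perm = 2000, seed = 1L,
                       tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(edge_alpha > 0, edge_alpha < component_alpha, component_alpha < 1, n_perm >= 100)
  structure(
    list(
      edge_alpha = edge_alpha, component_alpha = component_alpha,
      n_perm = as.integer(n_perm), seed = as.integer(seed), tail = tail
    ),
    class = "nbs_config"
  )
}

# Stack the upper triangles of a list of PLV matrices: subjects x edges.
stack_upper <- function(mats) {
  vals <- lapply(mats, function(m) {
    v <- if (inherits(m, "plv_matrix")) m$values else as.matrix(m)
    v[upper.tri(v)]
  })
  do.call(rbind, vals)
}

check_paired_input <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  la <- if (inherits(a[[1]], "plv_matrix")) a[[1]]$labels else rownames(as.matrix(a[[1]]))
  lb <- if (inherits(b[[1]], "plv_matrix")) b[[1]]$labels else rownames(as.matrix(b[[1]]))
  if (!is.null(la) && !is.null(lb) && !identical(la, lb)) {
    stop_plvnet("paired connectome input: region labels differ between groups")
  }
  la
}

paired_t_edges <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s2 <- (colSums(D^2) - n * m^2) / (n - 1)
  s2[s2 < 1e-24] <- 0
  # identical inputs (all differences zero) carry no evidence: t = 0, p = 1;
  # constant non-zero differences have no defined t and are flagged (NA)
  tt <- ifelse(s2 > 0, m / sqrt(s2 / n), ifelse(abs(m) < 1e-12, 0, NA_real_))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1), df = n - 1)
}

edge_vec_to_matrix <- function(v, n, labels, fill = 0) {
  m <- matrix(fill, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Edgewise paired t-tests between two matched sets of connectomes
#'
#' For every region pair, a paired t statistic over subjects' PLV differences
#' `a - b`; computed on the upper triangle and mirrored. Edges with zero
#' difference variance have no defined t; they are returned as `NA` and
#' flagged.
#'
#' @param a,b lists of [plv_matrix()] (or plain matrices) in matched subject
#'   order, length >= 3
#' @return list with symmetric `t` and `p` matrices (diagonal `NA`),
#'   `df`, and `flagged` (logical matrix of zero-variance edges)
#' @export
edgewise_paired_t <- function(a, b) {
  labels <- check_paired_input(a, b)
  D <- stack_upper(a) - stack_upper(b)
  res <- paired_t_edges(D)
  n_reg <- (1 + sqrt(1 + 8 * ncol(D))) / 2
  tmat <- edge_vec_to_matrix(res$t, n_reg, labels, fill = NA_real_)
  pmat <- edge_vec_to_matrix(res$p, n_reg, labels, fill = NA_real_)
  diag(tmat) <- NA_real_
  diag(pmat) <- NA_real_
  flagged <- edge_vec_to_matrix(as.numeric(is.na(res$t)), n_reg, labels) > 0
  diag(flagged) <- FALSE
  list(t = tmat, p = pmat, df = res$df, flagged = flagged)
}

# Largest connected component, measured in edges, of an edge subset
# (union-find over the incident nodes).
max_component_edges <- function(ei, ej) {
  k <- length(ei)
  if (k == 0L) return(0L)
  nodes <- unique(c(ei, ej))
  id <- match(c(ei, ej), nodes)
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_len(k)) {
    ra <- find(id[e])
    rb <- find(id[k + e])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(id[seq_len(k)], find, integer(1))
  max(tabulate(roots))
}

component_membership <- function(ei, ej) {
  k <- length(ei)
  nodes <- unique(c(ei, ej))
  id <- match(c(ei, ej), nodes)
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_len(k)) {
    ra <- find(id[e])
    rb <- find(id[k + e])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(id[seq_len(k)], find, integer(1))
}

sign_flip_matrix <- function(n_subjects, n_perm, seed) {
  if (2^n_subjects <= n_perm) {
    # full enumeration: the permutation test is exact
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_subjects)))
    dimnames(S) <- NULL
    list(S = S, exact = TRUE)
  } else {
    S <- with_seed(
      seed,
      matrix(sample(c(-1, 1), n_subjects * n_perm, replace = TRUE),
        nrow = n_perm
      )
    )
    list(S = S, exact = FALSE)
  }
}

perm_max_sizes <- function(S, D, t_crit, tail, ei, ej) {
  n <- ncol(S)
  ssq <- colSums(D^2)
  out <- numeric(nrow(S))
  for (p in seq_len(nrow(S))) {
    m <- as.numeric(S[p, ] %*% D) / n
    s2 <- (ssq - n * m^2) / (n - 1)
    s2[s2 <= 0] <- Inf
    tt <- m / sqrt(s2 / n)
    out[p] <- switch(tail,
      greater = max_component_edges(ei[tt > t_crit], ej[tt > t_crit]),
      less = max_component_edges(ei[tt < -t_crit], ej[tt < -t_crit]),
      two_sided = max(
        max_component_edges(ei[tt > t_crit], ej[tt > t_crit]),
        max_component_edges(ei[tt < -t_crit], ej[tt < -t_crit])
      )
    )
  }
  out
}

#' Network-Based Statistic paired test
#'
#' Edgewise paired t-tests, thresholding at `edge_alpha`, connected-component
#' formation among suprathreshold edges (separately per t sign for two-sided
#' testing), and a permutation null of maximal component size built by
#' within-subject sign flips of the paired difference matrices. When
#' `2^n_subjects <= n_perm` all sign patterns are enumerated and the test is
#' exact. Component corrected p-values use the standard
#' `(1 + #\{null >= observed\}) / (1 + n_perm)` estimator (or the exact
#' enumeration proportion).
#'
#' @param a,b matched lists of [plv_matrix()] per subject
#' @param cfg an [nbs_config()]
#' @return object of class `nbs_result`: `edge_t`, `edge_p`, `suprathreshold`
#'   (0/1 matrix), `components` (list of edge sets with sizes and corrected
#'   p), `null_max_sizes`, `exact`, `cfg`
#' @export
nbs_test <- function(a, b, cfg = nbs_config()) {
  stopifnot(inherits(cfg, "nbs_config"))
  labels <- check_paired_input(a, b)
  Da <- stack_upper(a)
  Db <- stack_upper(b)
  D <- Da - Db
  n <- nrow(D)
  n_reg <- (1 + sqrt(1 + 8 * ncol(D))) / 2
  if (is.null(labels)) labels <- paste0("R", seq_len(n_reg))
  ut <- which(upper.tri(matrix(0, n_reg, n_reg)), arr.ind = TRUE)
  ei <- ut[, 1]
  ej <- ut[, 2]

  obs <- paired_t_edges(D)
  usable <- !is.na(obs$t)
  df <- obs$df
  t_crit <- switch(cfg$tail,
    two_sided = stats::qt(1 - cfg$edge_alpha / 2, df),
    stats::qt(1 - cfg$edge_alpha, df)
  )

  supra_pos <- usable & obs$t > t_crit & cfg$tail %in% c("two_sided", "greater")
  supra_neg <- usable & obs$t < -t_crit & cfg$tail %in% c("two_sided", "less")

  components <- list()
  for (sgn in c(1, -1)) {
    sel <- if (sgn == 1) which(supra_pos) else which(supra_neg)
    if (!length(sel)) next
    memb <- component_membership(ei[sel], ej[sel])
    for (cid in unique(memb)) {
      edges_idx <- sel[memb == cid]
      components[[length(components) + 1L]] <- list(
        edges = cbind(labels[ei[edges_idx]], labels[ej[edges_idx]]),
        edge_index = cbind(ei[edges_idx], ej[edges_idx]),
        size = length(edges_idx),
        sign = sgn
      )
    }
  }

  # null distribution over the usable edges only
  Du <- D[, usable, drop = FALSE]
  sf <- sign_flip_matrix(n, cfg$n_perm, cfg$seed)
  null_max <- perm_max_sizes(sf$S, Du, t_crit, cfg$tail, ei[usable], ej[usable])

  for (i in seq_along(components)) {
    sz <- components[[i]]$size
    components[[i]]$p_corrected <- if (sf$exact) {
      mean(null_max >= sz)
    } else {
      (1 + sum(null_max >= sz)) / (1 + length(null_max))
    }
  }
  ord <- order(vapply(components, `[[`, numeric(1), "p_corrected"))
  components <- components[ord]

  tmat <- edge_vec_to_matrix(obs$t, n_reg, labels, fill = NA_real_)
  diag(tmat) <- NA_real_
  supra <- edge_vec_to_matrix(as.numeric(supra_pos | supra_neg), n_reg, labels)
  structure(
    list(
      edge_t = tmat,
      edge_p = edge_vec_to_matrix(obs$p, n_reg, labels, fill = NA_real_),
      suprathreshold = supra,
      components = components,
      null_max_sizes = null_max,
      exact = sf$exact,
      n_flagged = sum(!usable),
      df = df, cfg = cfg
    ),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  sig <- vapply(x$components, function(co) co$p_corrected < x$cfg$component_alpha, logical(1))
  cat(sprintf(
    "<nbs_result> %d suprathreshold edge(s), %d component(s) (%d significant at p < %g), %s permutations%s\n",
    sum(x$suprathreshold) / 2, length(x$components), sum(sig),
    x$cfg$component_alpha, length(x$null_max_sizes),
    if (x$exact) " (exact enumeration)" else ""
  ))
  invisible(x)
}

#' Significant components of an NBS result
#' @param x an `nbs_result`
#' @param alpha corrected alpha (defaults to the config's component alpha)
#' @return list of significant components
#' @export
nbs_significant <- function(x, alpha = x$cfg$component_alpha) {
  Filter(function(co) co$p_corrected < alpha, x$components)
}

#' Write an NBS result as JSON plus a significant-edge TSV
#'
#' @param x an `nbs_result`
#' @param path JSON path; the edge list goes to `<path>.edges.tsv`
#' @return `path`, invisibly
#' @export
write_nbs_result <- function(x, path) {
  comps <- lapply(x$components, function(co) {
    list(
      size = co$size, sign = co$sign, p_corrected = co$p_corrected,
      edges = apply(co$edges, 1, paste, collapse = "--")
    )
  })
  jsonlite::write_json(
    list(
      components = comps, null_max_sizes = x$null_max_sizes,
      exact = x$exact, n_flagged = x$n_flagged,
      cfg = unclass(x$cfg)
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  sig <- nbs_significant(x)
  edges <- do.call(rbind, lapply(seq_along(sig), function(i) {
    data.frame(
      component = i,
      region_a = sig[[i]]$edges[, 1], region_b = sig[[i]]$edges[, 2],
      sign = sig[[i]]$sign, p_corrected = sig[[i]]$p_corrected
    )
  }))
  if (is.null(edges)) {
    edges <- data.frame(
      component = integer(), region_a = character(),
      region_b = character(), sign = integer(), p_corrected = numeric()
    )
  }
  utils::write.table(edges, paste0(path, ".edges.tsv"),
    sep = "\t",
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
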