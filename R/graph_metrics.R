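#' Sparsity grid for network thresholding
#'
#' Arithmetic sequence of edge-density levels at which weighted connectivity is
#' binarized; defaults 0.06 to 0.50 in steps of 0.02 (23 levels).
#'
#' @param start,stop,step grid parameters
#' @return object of class `sparsity_grid` with a `levels` vector
#' @export
sparsity_grid <- function(start = 0.06, stop = 0.50, step = 0.02) {
  stopifnot(start > 0, stop < 1, step > 0, stop > start)
  levels <- seq(start, stop, by = step)
  structure(
    list(start = start, stop = stop, step = step, levels = levels),
    class = "sparsity_grid"
  )
}

#' Binarize a connectivity matrix at a target sparsity
#'
#' Retains exactly `round(s * N(N-1)/2)` strongest off-diagonal edges
#' (round-half-away-from-zero) and sets them to 1. Ties at the cut boundary
#' are broken deterministically by (weight descending, row index, column
#' index), so repeated calls give identical graphs.
#'
#' @param W a [plv_matrix()] or symmetric numeric matrix
#' @param s sparsity in `(0, 1)`: fraction of possible edges kept
#' @return object of class `binary_graph`: `adjacency` (0/1, zero diagonal),
#'   `labels`, `sparsity` (realized edge fraction), `n_edges`
#' @export
threshold_by_sparsity <- function(W, s) {
  vals <- if (inherits(W, "plv_matrix")) W$values else as.matrix(W)
  labels <- if (inherits(W, "plv_matrix")) W$labels else rownames(vals)
  n <- nrow(vals)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  stopifnot(s > 0, s < 1)
  m <- n * (n - 1) / 2
  k <- round_half_away(s * m)
  if (k < 1L) {
    stop_plvnet(sprintf("threshold_by_sparsity: sparsity %.3f keeps zero edges on %d nodes", s, n))
  }
  ut <- which(upper.tri(vals), arr.ind = TRUE)
  w <- vals[upper.tri(vals)]
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  A <- matrix(0L, n, n, dimnames = list(labels, labels))
  A[ut[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  structure(
    list(
      adjacency = A, labels = labels,
      sparsity = k / m, n_edges = as.integer(k)
    ),
    class = "binary_graph"
  )
}

#' Construct a binary graph directly from an adjacency matrix
#' @param A symmetric 0/1 matrix with zero diagonal
#' @param labels optional node labels
#' @return a `binary_graph`
#' @export
binary_graph <- function(A, labels = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  stopifnot(ncol(A) == n, all(A %in% c(0, 1)), all(diag(A) == 0), all(A == t(A)))
  if (is.null(labels)) {
    labels <- rownames(A)
    if (is.null(labels)) labels <- paste0("R", seq_len(n))
  }
  storage.mode(A) <- "integer"
  dimnames(A) <- list(labels, labels)
  m <- sum(A) / 2
  structure(
    list(
      adjacency = A, labels = as.character(labels),
      sparsity = if (n > 1) m / (n * (n - 1) / 2) else 0, n_edges = as.integer(m)
    ),
    class = "binary_graph"
  )
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}

graph_distances <- function(g) {
  igraph::distances(as_igraph(g), algorithm = "unweighted")
}

#' Average clustering coefficient
#'
#' `Cp = (1/N) * sum_i E_i / (D_i (D_i - 1) / 2)` where `E_i` counts edges
#' among the neighbours of node i and `D_i` is its degree; nodes of degree
#' below 2 contribute 0.
#'
#' @param g a `binary_graph`
#' @return Cp in `[0, 1]`
#' @export
clustering_coefficient <- function(g) {
  A <- g$adjacency
  n <- nrow(A)
  stopifnot(n >= 3)
  deg <- rowSums(A)
  tri2 <- diag(A %*% A %*% A) # = 2 * E_i
  ci <- ifelse(deg >= 2, tri2 / (deg * (deg - 1)), 0)
  mean(ci)
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected ordered node pairs; pairs in
#' different components are excluded from the average.
#'
#' @param g a `binary_graph`
#' @return Lp >= 1
#' @export
characteristic_path_length <- function(g) {
  stopifnot(nrow(g$adjacency) >= 2)
  if (g$n_edges == 0) stop_plvnet("characteristic_path_length: graph has no edges")
  d <- graph_distances(g)
  d <- d[row(d) != col(d)]
  mean(d[is.finite(d)])
}

#' Global efficiency
#'
#' `Eglob = 1/(N(N-1)) * sum_{i != j} 1 / L_ij`, with `1/L_ij = 0` for
#' disconnected pairs — well defined on disconnected networks.
#'
#' @param g a `binary_graph`
#' @return Eglob in `[0, 1]`
#' @export
global_efficiency <- function(g) {
  stopifnot(nrow(g$adjacency) >= 2)
  d <- graph_distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (nrow(d) * (nrow(d) - 1))
}

#' Local efficiency
#'
#' Node-averaged global efficiency of each node's neighbourhood subgraph
#' (the subgraph induced by its neighbours); nodes with fewer than two
#' neighbours contribute 0.
#'
#' @param g a `binary_graph`
#' @return Eloc in `[0, 1]`
#' @export
local_efficiency <- function(g) {
  A <- g$adjacency
  n <- nrow(A)
  stopifnot(n >= 2)
  eff <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    global_efficiency(binary_graph(A[nb, nb, drop = FALSE]))
  }, numeric(1))
  mean(eff)
}

#' Degree-preserving random-network null
#'
#' Mean clustering coefficient and characteristic path length over `n_random`
#' degree-preserving rewired surrogates (double-edge swaps, 10 x |E| attempted
#' swaps each). Every surrogate's degree sequence is asserted equal to the
#' input's. Reproducible from `seed`.
#'
#' @param g a `binary_graph` with at least one edge
#' @param n_random number of surrogates (default 1000)
#' @param seed integer seed
#' @return list `(c_random, l_random, n_random, seed)`
#' @export
random_null <- function(g, n_random = 1000, seed = 1L) {
  stopifnot(g$n_edges >= 1)
  ig <- as_igraph(g)
  deg0 <- sort(igraph::degree(ig))
  seeds <- derive_seeds(seed, n_random)
  cs <- numeric(n_random)
  ls <- numeric(n_random)
  niter <- 10L * g$n_edges
  for (i in seq_len(n_random)) {
    rg <- with_seed(seeds[i], igraph::rewire(ig, igraph::keeping_degseq(niter = niter)))
    if (!identical(sort(igraph::degree(rg)), deg0)) {
      stop_plvnet("random_null: surrogate degree sequence drifted (internal error)")
    }
    sg <- binary_graph(igraph::as_adjacency_matrix(rg, sparse = FALSE), labels = g$labels)
    cs[i] <- clustering_coefficient(sg)
    ls[i] <- characteristic_path_length(sg)
  }
  list(
    c_random = mean(cs), l_random = mean(ls),
    n_random = as.integer(n_random), seed = as.integer(seed)
  )
}

#' Small-world indices
#'
#' `gamma = Cp / Crandom`, `lambda = Lp / Lrandom`, `sigma = gamma / lambda`
#' (exact identity). `sigma > 1` indicates small-world organization.
#'
#' @param g a `binary_graph`
#' @param null a [random_null()] result
#' @return list `(gamma, lambda, sigma, cp, lp)`
#' @export
small_world <- function(g, null) {
  if (null$c_random <= 0 || null$l_random <= 0) {
    stop_plvnet("small_world: null means must be positive")
  }
  cp <- clustering_coefficient(g)
  lp <- characteristic_path_length(g)
  gamma <- cp / null$c_random
  lambda <- lp / null$l_random
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda, cp = cp, lp = lp)
}

trapz_mean <- function(x, y) {
  # trapezoidal area under y(x) divided by the x range: a grid-robust average;
  # levels where the metric is undefined (e.g. gamma with a zero null
  # clustering mean at very sparse thresholds) are dropped
  ok <- is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  sum(diff(x) * (y[-1] + y[-n]) / 2) / (x[n] - x[1])
}

#' Graph-metric profile over a sparsity grid
#'
#' Thresholds a weighted PLV matrix at every grid level, computes the six
#' metrics (Cp, Lp, Eglob, Eloc, gamma, lambda, sigma) per level, and
#' aggregates each metric across levels as the area under the
#' metric-versus-sparsity curve divided by the grid width (so a metric that is
#' constant across levels aggregates to that constant).
#'
#' @param W a [plv_matrix()] or weight matrix
#' @param grid a [sparsity_grid()]
#' @param n_random random-network surrogates per level (default 1000)
#' @param seed seed for the null streams (one substream per level)
#' @return object of class `metric_profile`: `per_level` data.frame (one row
#'   per sparsity level) and `aggregate` named vector
#' @export
metric_profile <- function(W, grid = sparsity_grid(), n_random = 1000, seed = 1L) {
  stopifnot(inherits(grid, "sparsity_grid"))
  level_seeds <- derive_seeds(seed, length(grid$levels))
  rows <- lapply(seq_along(grid$levels), function(i) {
    s <- grid$levels[i]
    g <- threshold_by_sparsity(W, s)
    null <- random_null(g, n_random = n_random, seed = level_seeds[i])
    cp <- clustering_coefficient(g)
    lp <- characteristic_path_length(g)
    # a triangle-free null (possible at very sparse levels) leaves gamma and
    # sigma undefined at that level
    gamma <- if (null$c_random > 0) cp / null$c_random else NA_real_
    lambda <- lp / null$l_random
    data.frame(
      sparsity = s, n_edges = g$n_edges,
      cp = cp, lp = lp,
      eglob = global_efficiency(g), eloc = local_efficiency(g),
      gamma = gamma, lambda = lambda, sigma = gamma / lambda
    )
  })
  per_level <- do.call(rbind, rows)
  metrics <- c("cp", "lp", "eglob", "eloc", "gamma", "lambda", "sigma")
  aggregate <- vapply(metrics, function(m) trapz_mean(per_level$sparsity, per_level[[m]]),
    numeric(1)
  )
  structure(
    list(
      per_level = per_level, aggregate = aggregate,
      n_random = as.integer(n_random), seed = as.integer(seed)
    ),
    class = "metric_profile"
  )
}

#' @export
print.metric_profile <- function(x, ...) {
  cat(sprintf(
    "<metric_profile> %d sparsity levels, %d nulls/level\naggregates: %s\n",
    nrow(x$per_level), x$n_random,
    paste(sprintf("%s=%.3f", names(x$aggregate), x$aggregate), collapse = " ")
  ))
  invisible(x)
}

#' Serialize a metric profile to JSON
#' @param mp a [metric_profile()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_metric_profile <- function(mp, path) {
  jsonlite::write_json(
    list(
      per_level = mp$per_level, aggregate = as.list(mp$aggregate),
      n_random = mp$n_random, seed = mp$seed
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
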