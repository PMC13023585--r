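# Brute-force graph oracles, deliberately independent of the package's
# implementation (no igraph, no shared helpers): plain BFS and pair/triple
# enumeration over adjacency matrices.

oracle_bfs_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (src in seq_len(n)) {
    frontier <- src
    dist <- 0
    visited <- rep(FALSE, n)
    visited[src] <- TRUE
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] == 1)) {
          if (!visited[w]) {
            visited[w] <- TRUE
            d[src, w] <- dist
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
  }
  d
}

oracle_cp <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) e <- e + A[nb[a], nb[b]]
    }
    vals[i] <- e / (k * (k - 1) / 2)
  }
  mean(vals)
}

oracle_lp <- function(A) {
  d <- oracle_bfs_distances(A)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_eglob <- function(A) {
  d <- oracle_bfs_distances(A)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(A)
  sum(inv) / (n * (n - 1))
}

oracle_eloc <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) next
    vals[i] <- oracle_eglob(A[nb, nb, drop = FALSE])
  }
  mean(vals)
}

# small named fixtures
graph_k <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  A
}

graph_star <- function(leaves) {
  A <- matrix(0L, leaves + 1, leaves + 1)
  A[1, 2:(leaves + 1)] <- 1L
  A[2:(leaves + 1), 1] <- 1L
  A
}

graph_path <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}

# triangle {1,2,3} plus pendant 4-1
graph_triangle_pendant <- function() {
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 3] <- A[1, 3] <- A[1, 4] <- 1L
  A + t(A) - diag(diag(A + t(A)))
  B <- matrix(0L, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(1, 4))) {
    B[e[1], e[2]] <- B[e[2], e[1]] <- 1L
  }
  B
}

graph_ring_lattice <- function(n, k) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(k / 2)) {
      a <- i
      b <- ((i + j - 1) %% n) + 1
      A[a, b] <- A[b, a] <- 1L
    }
  }
  A
}

random_symmetric_weights <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  diag(m) <- 1
  m
}

toy_partition_file <- function(n_per = c(SMN = 3, DAN = 2, SN = 2, CEN = 2, DMN = 3)) {
  labels <- unlist(lapply(names(n_per), function(nw) {
    sprintf("%s_%02d", nw, seq_len(n_per[[nw]]))
  }))
  nets <- rep(names(n_per), n_per)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(region_label = labels, network_label = nets),
    f,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  f
}

# band used throughout the cheap synthetic tests (shares the session-level
# calibration cache)
test_band <- function() default_bands()$alpha
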