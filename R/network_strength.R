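#' Read and validate a region-to-network partition
#'
#' The partition is a two-column TSV (`region_label`, `network_label`) mapping
#' each region to one of the five resting-state networks SMN, DAN, SN, CEN,
#' DMN. Validation reports the offending line number for duplicate regions,
#' unknown network labels, and networks with fewer than two regions.
#'
#' @param path TSV path
#' @return named character vector region -> network, class `network_partition`
#' @export
validate_partition <- function(path) {
  if (!file.exists(path)) stop_plvnet(sprintf("partition file not found: %s", path))
  df <- utils::read.table(path,
    sep = "\t", header = TRUE,
    col.names = c("region_label", "network_label"),
    stringsAsFactors = FALSE
  )
  allowed <- c("SMN", "DAN", "SN", "CEN", "DMN")
  dup <- which(duplicated(df$region_label))
  if (length(dup)) {
    stop_plvnet(sprintf(
      "partition: duplicated region '%s' at line %d",
      df$region_label[dup[1]], dup[1] + 1L
    ))
  }
  bad <- which(!df$network_label %in% allowed)
  if (length(bad)) {
    stop_plvnet(sprintf(
      "partition: unknown network label '%s' at line %d (allowed: %s)",
      df$network_label[bad[1]], bad[1] + 1L, paste(allowed, collapse = ", ")
    ))
  }
  counts <- table(df$network_label)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    stop_plvnet(sprintf(
      "partition: network(s) %s have fewer than 2 regions",
      paste(small, collapse = ", ")
    ))
  }
  p <- stats::setNames(df$network_label, df$region_label)
  class(p) <- "network_partition"
  p
}

#' The shipped default 78-region partition (synthetic stand-in)
#'
#' A synthetic five-network partition of 78 labelled regions with realistic
#' network sizes (SMN 14, DAN 14, SN 12, CEN 16, DMN 22), shipped for
#' surrogate runs. It is *not* an atlas-derived lookup; real analyses should
#' supply their own parcel-to-network table.
#'
#' @return a `network_partition`
#' @export
default_partition <- function() {
  validate_partition(
    system.file("extdata", "partition_78_synthetic.tsv", package = "plvnet")
  )
}

partition_for <- function(W, p) {
  if (!all(W$labels %in% names(p))) {
    missing <- setdiff(W$labels, names(p))
    stop_plvnet(sprintf(
      "partition does not cover region(s): %s",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  unname(unclass(p)[W$labels])
}

#' Total average PLV, excluding self-connections
#'
#' Mean over the strict upper triangle: the global index of phase
#' synchronization across the network.
#'
#' @param W a [plv_matrix()] or symmetric matrix
#' @return mean off-diagonal PLV
#' @export
total_average_plv <- function(W) {
  v <- if (inherits(W, "plv_matrix")) W$values else as.matrix(W)
  stopifnot(nrow(v) >= 2)
  mean(v[upper.tri(v)])
}

#' Within-network connection strength
#'
#' Mean PLV over unordered region pairs with both regions inside `net`.
#'
#' @param W a [plv_matrix()]
#' @param p a `network_partition` covering the matrix labels
#' @param net network label
#' @return mean within-network PLV
#' @export
within_strength <- function(W, p, net) {
  membership <- partition_for(W, p)
  idx <- which(membership == net)
  if (length(idx) < 2) {
    stop_plvnet(sprintf("within_strength: network '%s' has fewer than 2 regions in this matrix", net))
  }
  v <- W$values[idx, idx]
  mean(v[upper.tri(v)])
}

#' Between-network connection strength
#'
#' Mean PLV over pairs with one region in `net_a` and one in `net_b`;
#' symmetric in its network arguments.
#'
#' @inheritParams within_strength
#' @param net_a,net_b distinct network labels
#' @return mean between-network PLV
#' @export
between_strength <- function(W, p, net_a, net_b) {
  stopifnot(net_a != net_b)
  membership <- partition_for(W, p)
  ia <- which(membership == net_a)
  ib <- which(membership == net_b)
  if (!length(ia)) stop_plvnet(sprintf("between_strength: unknown or empty network '%s'", net_a))
  if (!length(ib)) stop_plvnet(sprintf("between_strength: unknown or empty network '%s'", net_b))
  mean(W$values[ia, ib])
}

#' Min-max normalization
#'
#' `(x - min) / (max - min)`: order-preserving map of a collection onto
#' `[0, 1]`; invariant to positive affine transforms of the input.
#'
#' @param values numeric vector with at least two distinct values
#' @return normalized vector in `[0, 1]`
#' @export
minmax_normalize <- function(values) {
  rng <- range(values)
  if (rng[1] == rng[2]) {
    stop_plvnet(sprintf(
      "minmax_normalize: degenerate span (all %d values equal %g)",
      length(values), rng[1]
    ))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Strength table for a group dataset
#'
#' Per subject x condition x time x band: the total average PLV, the five
#' within-network strengths, and the ten between-network strengths over the
#' partition. Optionally min-max normalizes each strength measure per band
#' across all subject/condition/time values, so the four compared design
#' cells share one scale.
#'
#' @param gd a `group_dataset`
#' @param partition a `network_partition`
#' @param normalize min-max normalize each measure within band (default TRUE)
#' @return long data.frame: subject, condition, time, band, measure
#'   (`total_average`, `within_<NET>`, `between_<A>_<B>`), value and (if
#'   requested) value_normalized
#' @export
strength_table <- function(gd, partition, normalize = TRUE) {
  nets <- c("SMN", "DAN", "SN", "CEN", "DMN")
  pairs <- utils::combn(nets, 2)
  rows <- lapply(seq_len(nrow(gd$index)), function(i) {
    W <- gd$matrices[[gd$index$key[i]]]
    vals <- c(
      total_average = total_average_plv(W),
      stats::setNames(
        vapply(nets, function(nw) within_strength(W, partition, nw), numeric(1)),
        paste0("within_", nets)
      ),
      stats::setNames(
        vapply(seq_len(ncol(pairs)), function(k) {
          between_strength(W, partition, pairs[1, k], pairs[2, k])
        }, numeric(1)),
        paste0("between_", pairs[1, ], "_", pairs[2, ])
      )
    )
    data.frame(
      gd$index[i, c("subject", "condition", "time", "band")],
      measure = names(vals), value = unname(vals),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (normalize) {
    out$value_normalized <- NA_real_
    for (b in unique(out$band)) {
      for (m in unique(out$measure)) {
        sel <- out$band == b & out$measure == m
        out$value_normalized[sel] <- minmax_normalize(out$value[sel])
      }
    }
  }
  out
}
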