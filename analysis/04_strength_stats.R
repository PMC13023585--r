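#!/usr/bin/env Rscript
# Stage 4 — within/between-network strengths and nonparametric statistics.
#
# Aggregates each PLV matrix into the total average PLV, five within-network
# strengths and ten between-network strengths over the five-network partition
# (min-max normalized per band across all subject/condition/time values),
# then compares the four design cells per measure with the Friedman omnibus
# test and Dunn's post hoc pairs (Bonferroni), plus paired t-tests on the
# total average PLV for the post-vs-pre contrast in each condition.

suppressMessages(library(plvnet))

gd <- readRDS("scratch/group_dataset.rds")
out_dir <- "results/analysis"

# the simulated labels R1..R30 need a partition: carve the five networks
# proportionally over the simulated regions
n <- gd$design$n_regions
sizes <- round(n * c(SMN = 14, DAN = 14, SN = 12, CEN = 16, DMN = 22) / 78)
sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
pfile <- file.path(out_dir, "partition_simulated.tsv")
write.table(
  data.frame(
    region_label = gd$design$labels,
    network_label = rep(names(sizes), sizes)
  ),
  pfile,
  sep = "\t", row.names = FALSE, quote = FALSE
)
partition <- validate_partition(pfile)

st <- strength_table(gd, partition)
write.csv(st, file.path(out_dir, "strengths.csv"), row.names = FALSE)

fried_rows <- list()
for (b in unique(st$band)) {
  for (m in unique(st$measure)) {
    sub <- st[st$band == b & st$measure == m, ]
    cells <- split(sub, interaction(sub$condition, sub$time))
    blocks <- do.call(cbind, lapply(cells, function(cl) cl$value[order(cl$subject)]))
    fr <- friedman_test(blocks)
    dn <- dunn_posthoc(blocks)
    fried_rows[[length(fried_rows) + 1L]] <- data.frame(
      band = b, measure = m, chi2 = fr$statistic, df = fr$df, p = fr$p.value,
      best_pair = paste(dn$cond_a[which.min(dn$p_adj)], dn$cond_b[which.min(dn$p_adj)], sep = " vs "),
      best_pair_p_adj = min(dn$p_adj)
    )
  }
}
fried_tab <- do.call(rbind, fried_rows)
write.csv(fried_tab, file.path(out_dir, "friedman_dunn.csv"), row.names = FALSE)

tt_rows <- list()
for (cond in gd$design$conditions) {
  for (b in names(gd$design$bands)) {
    post <- vapply(get_cell(gd, b, cond, "post"), total_average_plv, numeric(1))
    pre <- vapply(get_cell(gd, b, cond, "pre"), total_average_plv, numeric(1))
    pt <- paired_t(post, pre)
    tt_rows[[length(tt_rows) + 1L]] <- data.frame(
      condition = cond, band = b, mean_post = mean(post), mean_pre = mean(pre),
      t = pt$t, df = pt$df, p = pt$p.value
    )
    message(sprintf(
      "total average PLV, %s / %s: post %.3f vs pre %.3f (t(%d) = %.2f, p = %.4g)",
      cond, b, mean(post), mean(pre), pt$df, pt$t, pt$p.value
    ))
  }
}
tt_tab <- do.call(rbind, tt_rows)
write.csv(tt_tab, file.path(out_dir, "total_plv_paired_t.csv"), row.names = FALSE)

n_sig <- sum(fried_tab$p < 0.05)
message(sprintf(
  "%d of %d strength measures show a Friedman omnibus difference at p < 0.05.",
  n_sig, nrow(fried_tab)
))
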