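#!/usr/bin/env Rscript
# Step 4 — erosion of branching history.
#
# For each replicate, bins the pre-event tree's branching ages (1000-update
# bins at desk scale), prunes every later tree at the event-start cutoff and
# computes per-bin percent retention; aggregates per treatment at the
# immediate post-event snapshot; tabulates root-age histograms per snapshot;
# and counts genotype originations / extinctions / persistences across the
# event window.  Writes results/retention.tsv, results/retention_summary.tsv,
# results/root_age_histogram.tsv and results/turnover.tsv.

suppressPackageStartupMessages(library(phyloerosion))

bin_width <- 1000
cutoff <- desk_profile("control")$schedule$pre_updates
event_end <- cutoff + desk_profile("control")$schedule$press_duration
tree_dir <- file.path("results", "trees")
manifest <- utils::read.table(file.path(tree_dir, "manifest.tsv"),
                              sep = "\t", header = TRUE)

ret_rows <- list()
for (rep_id in unique(manifest$replicate)) {
  sub <- manifest[manifest$replicate == rep_id, ]
  pre <- sub[sub$snapshot == "pre", ]
  if (is.na(pre$path)) next
  pre_tree <- from_newick(readLines(pre$path))
  pre_b <- bin_node_ages(ltt(pre_tree)$branching_ages, bin_width)
  for (i in which(sub$snapshot != "pre")) {
    ages <- if (is.na(sub$path[i])) numeric(0) else
      prune_nodes_after(ltt(from_newick(readLines(sub$path[i])))$branching_ages,
                        cutoff)
    tb <- percent_retention(pre_b, bin_node_ages(ages, bin_width))
    tb$replicate <- rep_id
    tb$snapshot <- sub$snapshot[i]
    ret_rows[[length(ret_rows) + 1L]] <- tb
  }
}
retention <- do.call(rbind, ret_rows)
retention$treatment <- sub("_rep[0-9]+$", "", retention$replicate)
utils::write.table(retention, file.path("results", "retention.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

summaries <- list()
for (tr in unique(retention$treatment)) {
  sub <- retention[retention$treatment == tr & retention$snapshot == "post", ]
  tables <- split(sub, sub$replicate)
  if (length(tables) < 2L) next
  agg <- aggregate_retention(tables)
  agg$treatment <- tr
  summaries[[tr]] <- agg
  deep <- vapply(tables, deep_bin_retention, 0, cutoff = cutoff)
  cat(sprintf("%-13s post-event: mean retention %5.1f%% | deep third %5.1f%%\n",
              tr, mean(sub$retention, na.rm = TRUE),
              mean(deep, na.rm = TRUE)))
}
utils::write.table(do.call(rbind, summaries),
                   file.path("results", "retention_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

hist_in <- manifest[!is.na(manifest$root_age), ]
h <- root_age_histogram(
  data.frame(timepoint = paste(sub("_rep[0-9]+$", "", hist_in$replicate),
                               hist_in$snapshot, sep = ":"),
             root_age = hist_in$root_age),
  bin_width = bin_width, event_window = c(cutoff, event_end))
utils::write.table(h$counts, file.path("results", "root_age_histogram.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

turn_rows <- list()
for (log_path in list.files(file.path("results", "sim"),
                            pattern = "_rep[0-9]+\\.tsv$", full.names = TRUE)) {
  log <- read_genealogy_tsv(log_path)
  tc <- turnover_counts(log, c(cutoff, event_end))
  turn_rows[[length(turn_rows) + 1L]] <- data.frame(
    replicate = sub("\\.tsv$", "", basename(log_path)),
    t0 = cutoff, t1 = event_end,
    originations = tc[["originations"]],
    extinctions = tc[["extinctions"]],
    persistences = tc[["persistences"]])
}
utils::write.table(do.call(rbind, turn_rows),
                   file.path("results", "turnover.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote retention, summary, root-age histogram and turnover tables\n")
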