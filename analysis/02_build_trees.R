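#!/usr/bin/env Rscript
# Step 2 — prune genealogies to phylogenies of extant genotypes.
#
# For every simulated replicate and snapshot, builds the ultrametric tree of
# the genotypes extant at that snapshot and writes it as newick under
# results/trees/, plus a manifest (results/trees/manifest.tsv) with tip
# counts and root ages.  Snapshots with fewer than two extant genotypes are
# degenerate and recorded as such.

suppressPackageStartupMessages(library(phyloerosion))

sim_dir <- file.path("results", "sim")
out <- file.path("results", "trees")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

logs <- list.files(sim_dir, pattern = "_rep[0-9]+\\.tsv$", full.names = TRUE)
manifest <- list()
for (log_path in logs) {
  stem <- sub("\\.tsv$", "", basename(log_path))
  log <- read_genealogy_tsv(log_path)
  snaps <- utils::read.table(sub("\\.tsv$", "_snapshots.tsv", log_path),
                             sep = "\t", header = TRUE)
  for (lab in unique(snaps$label)) {
    sub <- snaps[snaps$label == lab, ]
    tree <- tryCatch(
      build_tree(log, sub$update[1], extant = unique(sub$genotype_id)),
      error = function(e) NULL)
    nwk_path <- file.path(out, sprintf("%s_%s.nwk", stem, lab))
    if (!is.null(tree)) writeLines(to_newick(tree), nwk_path)
    manifest[[length(manifest) + 1L]] <- data.frame(
      replicate = stem, snapshot = lab, update = sub$update[1],
      path = if (is.null(tree)) NA_character_ else nwk_path,
      n_tips = if (is.null(tree)) NA_integer_ else tree$n_tips,
      root_age = if (is.null(tree)) NA_real_ else tree$root_age,
      root_host = if (is.null(tree)) NA_character_ else tree$root_host)
  }
}
manifest <- do.call(rbind, manifest)
utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("built %d trees (%d degenerate) from %d replicates\n",
            sum(!is.na(manifest$path)), sum(is.na(manifest$path)),
            length(logs)))
cat(sprintf("median pre-event tips: %d\n",
            as.integer(stats::median(
              manifest$n_tips[manifest$snapshot == "pre"], na.rm = TRUE))))
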