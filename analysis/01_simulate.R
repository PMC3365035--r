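#!/usr/bin/env Rscript
# Step 1 — simulate the digital communities.
#
# Runs every treatment (control, weak/strong pulse, weak/strong press) at the
# desk scale (400 organisms, 10,000 + 1,000 + 10,000 updates) for REPLICATES
# seeded replicates each, and writes per replicate:
#   results/sim/<treatment>_rep<k>.tsv            genealogy log
#   results/sim/<treatment>_rep<k>_snapshots.tsv  extant genotypes per snapshot
#
# Environment overrides: REPLICATES (default 6), BASE_SEED (default 20).

suppressPackageStartupMessages(library(phyloerosion))

n_rep <- as.integer(Sys.getenv("REPLICATES", "6"))
base_seed <- as.integer(Sys.getenv("BASE_SEED", "20"))
out <- file.path("results", "sim")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

treatments <- c("control", "pulse-strong", "pulse-weak", "press-strong",
                "press-weak")
manifest <- experiment_manifest(treatments, n_replicates = n_rep,
                                base_seed = base_seed, profile = "desk")

n_failed <- 0L
for (tr in treatments) {
  prof <- desk_profile(tr)
  for (r in seq_len(n_rep)) {
    seed <- replicate_seed(manifest, tr, r)
    exp <- run_experiment(prof$config, prof$schedule, seed = seed)
    if (exp$failed) { n_failed <- n_failed + 1L; next }
    stem <- file.path(out, sprintf("%s_rep%02d", tr, r))
    write_genealogy_tsv(exp$log, paste0(stem, ".tsv"))
    snaps <- do.call(rbind, lapply(seq_len(nrow(exp$snapshots)), function(i) {
      lab <- exp$snapshots$label[i]
      data.frame(label = lab, update = exp$snapshots$update[i],
                 genotype_id = unique(exp$populations[[lab]]))
    }))
    utils::write.table(snaps, paste0(stem, "_snapshots.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cat(sprintf("%s rep %d (seed %d): %d genotypes, %d extant pre-event\n",
                tr, r, seed, nrow(exp$log),
                sum(snaps$label == "pre")))
  }
}
cat(sprintf("done: %d treatments x %d replicates, %d failed\n",
            length(treatments), n_rep, n_failed))
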