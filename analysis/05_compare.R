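#!/usr/bin/env Rscript
# Step 5 — treatment comparisons.
#
# ANOVA with Tukey-HSD multiple comparisons on per-replicate deep-bin
# retention and on gamma (the latter restricted to replicates that kept the
# pre-event root, to avoid comparing trees of very different heights), and
# Kruskal-Wallis with Tukey-type rank comparisons on noncumulative
# stemminess, split by root retention.  Letters shared between treatments
# mean "not significantly different after correction".
# Writes results/comparisons.tsv.

suppressPackageStartupMessages(library(phyloerosion))

metrics <- utils::read.table(file.path("results", "metrics.tsv"),
                             sep = "\t", header = TRUE)
retention <- utils::read.table(file.path("results", "retention.tsv"),
                               sep = "\t", header = TRUE)
cutoff <- desk_profile("control")$schedule$pre_updates
rows <- list()
show <- function(name, cmp) {
  cat(sprintf("%s: omnibus p = %.4g\n", name, cmp$p_value))
  for (g in names(cmp$letters))
    cat(sprintf("   %-13s %s\n", g, cmp$letters[g]))
  rows[[length(rows) + 1L]] <<- data.frame(
    test = name, group = names(cmp$letters), letters = unname(cmp$letters),
    omnibus_p = cmp$p_value)
}

post_ret <- retention[retention$snapshot == "post", ]
deep <- do.call(rbind, lapply(split(post_ret, post_ret$replicate), function(d)
  data.frame(treatment = d$treatment[1],
             deep = deep_bin_retention(d, cutoff))))
deep <- deep[!is.na(deep$deep), ]
groups <- split(deep$deep, deep$treatment)
groups <- groups[lengths(groups) >= 2L]
if (length(groups) >= 2L)
  show("deep_bin_retention_post_anova", anova_tukey(groups))

end_label <- metrics$snapshot[which.max(metrics$update)]
endm <- metrics[metrics$snapshot == end_label, ]
gam <- endm[endm$root_retained %in% TRUE & !is.na(endm$gamma), ]
groups <- split(gam$gamma, gam$treatment)
groups <- groups[lengths(groups) >= 2L]
if (length(groups) >= 2L)
  show("gamma_end_root_retained_anova", anova_tukey(groups))

for (kept in c(TRUE, FALSE)) {
  sub <- endm[endm$root_retained %in% kept & !is.na(endm$ncs_rohlf), ]
  groups <- split(sub$ncs_rohlf, sub$treatment)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) >= 2L)
    show(paste0("ncs_end_kruskal_root_",
                if (kept) "retained" else "lost"),
         kruskal_tukey(groups))
}

utils::write.table(do.call(rbind, rows),
                   file.path("results", "comparisons.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/comparisons.tsv\n")
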