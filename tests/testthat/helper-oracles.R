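# Independent oracles used across the suite.  These re-derive quantities by
# different machinery than the package (unit-step sweeps, explicit
# ancestor-path enumeration) and must stay independent of the code they check.

# Gamma by sweeping time in unit steps: lineage counts re-derived by counting
# branching ages at or before each step.  Requires integer ages.
gamma_unit_sweep <- function(branching_ages, sample_time) {
  ages <- sort(branching_ages)
  n <- length(ages) + 1L
  stopifnot(n >= 3L, all(ages == round(ages)), sample_time == round(sample_time))
  ts <- seq(ages[1L], sample_time - 1L)          # unit intervals [t, t+1)
  k <- 1L + findInterval(ts, ages)               # lineages alive in each step
  T_tot <- sum(k)
  A <- vapply(2:(n - 1L), function(i) sum(k[ts < ages[i]]), 0)
  (mean(A) - T_tot / 2) / (T_tot * sqrt(1 / (12 * (n - 2L))))
}

# Pairwise MRCA ages by explicit enumeration of root-to-tip ancestor paths:
# two tips diverge at the origin of whichever path first leaves their deepest
# shared genotype (the tip staying in that genotype contributes +Inf).
brute_force_mrca <- function(log, extant) {
  extant <- as.character(extant)
  ids <- as.character(log$genotype_id)
  parent_of <- function(g) {
    p <- log$parent_id[match(g, ids)]
    if (is.na(p)) NA_character_ else as.character(p)
  }
  path <- function(g) {
    p <- character(0)
    while (!is.na(g)) { p <- c(g, p); g <- parent_of(g) }
    p
  }
  paths <- lapply(extant, path)
  n <- length(extant)
  M <- matrix(NA_real_, n, n, dimnames = list(extant, extant))
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      pa <- paths[[a]]; pb <- paths[[b]]
      m <- min(length(pa), length(pb))
      shared <- which(pa[seq_len(m)] == pb[seq_len(m)])
      k <- max(shared)
      ta <- if (length(pa) > k) log$origin_update[match(pa[k + 1L], ids)] else Inf
      tb <- if (length(pb) > k) log$origin_update[match(pb[k + 1L], ids)] else Inf
      M[a, b] <- M[b, a] <- min(ta, tb)
    }
  }
  M
}

# MRCA-age matrix implied by a phylo_eco tree (ultrametric, so the cophenetic
# distance between two tips is twice the time back to their MRCA).
tree_mrca_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree$phylo)
  m <- tree$sample_time - d / 2
  diag(m) <- NA_real_
  m[tree$tip_genotypes, tree$tip_genotypes, drop = FALSE]
}
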