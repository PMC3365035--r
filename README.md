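# phyloerosion

Tools for asking how mass extinctions erode the deep branching history of
phylogenies, using a closed model system in which the answer is exactly
observable.  The package simulates communities of asexual digital replicators
competing for a cascade of depletable cross-feeding resources, subjects them
to **pulse** extinctions (instantaneous culls with survivors drawn at random
from the viable organisms) and **press** extinctions (windows of drastically
reduced basal resource inflows, whose selectivity is emergent), prunes the
complete genotype genealogy to the ultrametric phylogeny of the genotypes
extant at any sampling time, and quantifies the loss of evolutionary history.

It is aimed at researchers in phylogenetics, macroevolution and artificial
life who want a reproducible, fully observable test bed for tree-shape
statistics under known extinction regimes.

## What it measures

For an ultrametric tree with `n` tips, branching times carry lineage counts
`k` through internode intervals `g_k` (multifurcations contribute
simultaneous splits with zero-length intervals).  With

    T   = sum_{k=2..n} k * g_k
    A_i = sum_{k=2..i} k * g_k

the **Pybus–Harvey gamma** statistic is

    gamma = [ (1/(n-2)) * sum_{i=2..n-1} A_i  -  T/2 ] / [ T * sqrt(1/(12(n-2))) ]

(negative = branching concentrated rootward; asymptotically standard normal
under a pure birth process).  **Noncumulative stemminess** scores each
internal non-root node's stem `l_j` against its immediately subtended
branches: the bounded Rohlf form `l_j / (l_j + sum l_c)` in [0, 1] (default)
and an inverse-ratio form `sum l_c / l_j` that can exceed 1.  The package
also tracks **root ages** and root retention, per-bin **percent retention**
of temporally binned branching events against the pre-extinction reference,
root-gap distances `d1`/`d2`, and genotype turnover, and compares treatments
with ANOVA/Tukey-HSD and Kruskal–Wallis/Tukey-type rank tests summarized as
compact letter displays.

## A worked example

A strong press at desk scale (400 organisms; 10,000 updates of history, a
1,000-update crisis with basal inflows at 1%, 10,000 updates of recovery):

```r
library(phyloerosion)
prof <- desk_profile("press-strong")
exp  <- run_experiment(prof$config, prof$schedule, seed = 1)

pre <- build_tree(exp$log, 10000, extant = unique(exp$populations[["pre"]]))
end <- build_tree(exp$log, 21000, extant = unique(exp$populations[["rec10000"]]))
pre
#> <phylo_eco> 77 tips, 74 internal nodes | root age 28 | sampled at 10000
end
#> <phylo_eco> 73 tips, 68 internal nodes | root age 10666 | sampled at 21000
root_retained(pre, end)
#> [1] FALSE
c(gamma = pybus_harvey_gamma(pre), ncs = ncs(pre)$value)
#>     gamma       ncs
#> 12.978620  0.461841
c(snapshot_mean_traits(exp, "pre"), snapshot_mean_traits(exp, "post"))
#> [1] 6.01 0.01
```

The pre-extinction community coexists as trait-rich specialist clades whose
common ancestor dates to update 28 — nearly the whole run deep.  The press
collapses the resource cascade: trait-poor "disaster taxa" sweep (mean traits
6.01 → 0.01), every pre-extinction branching event is lost, and the
end-of-run tree's root originates *inside* the crisis window (update 10,666).
A control replicate with the same machinery typically keeps its root and
nearly 100% of deep branching events; the weak treatments sit in between.
The positive gamma with long basal branches — branching concentrated at the
tips — is the expected signature of near-neutral genotypic cladogenesis.

The full workflow is in `analysis/`:

    01_simulate.R      simulate all five treatments, write genealogy logs
    02_build_trees.R   prune genealogies to newick phylogenies per snapshot
    03_tree_metrics.R  gamma, stemminess, root ages and gaps per snapshot
    04_retention.R     binned retention, root-age histograms, turnover
    05_compare.R       ANOVA/Tukey and Kruskal-Wallis letter displays

Each script writes its tables under `results/` and prints a short summary;
`REPLICATES` and `BASE_SEED` environment variables control the batch.

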