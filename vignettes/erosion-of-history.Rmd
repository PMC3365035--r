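---
title: "Measuring erosion of evolutionary history under pulse and press extinctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring erosion of evolutionary history under pulse and press extinctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloerosion)
```

## The question

Mass extinctions remove more than standing diversity: they can erase the deep
branching history recorded in the phylogeny of the survivors.  Whether a
*random* extinction (an instantaneous cull that spares survivors by lot) and a
*selective* extinction (a prolonged environmental crisis that survivors must
adapt through) leave distinguishable long-term signatures in tree shape is
hard to ask of the fossil record, because we rarely know which kind of event
occurred.  This package asks it of a closed model system instead: an
individual-based community of asexual digital replicators whose complete
genealogy is observable, so that the phylogeny of the survivors can be
extracted exactly at any time point, before and after an engineered
extinction.

## The digital ecology

The community holds a fixed number of organisms (3600 at full scale; 400 in
the reduced "desk" profile used throughout the tests).  Each organism's
genotype is a pair (trait bit-vector over nine resource-linked functions,
neutral tag).  Resources form a cross-feeding cascade: only the two basal
resources flow in from outside (100 units/update each by default); every
other resource arises solely as a by-product, one unit per three units
consumed one level up.  Both basal functions feed the three second-level
functions; the first second-level function feeds the third level, which feeds
the deepest function.  Rewards double with cascade depth
(`2^(level-1)`, i.e. 1, 1, 2, 2, 2, 4, 4, 4, 8), so deep functions pay more
but depend on the whole chain below them.

One update proceeds as: resource decay (1% per update) and inflow; equal
division of a 25% uptake share of each resource among the organisms
performing its function, crediting merit `reward * consumed`; fitness
`(base_merit + merit) / (1 + trait_cost * n_traits)`; a Poisson number of
births (0.2 per organism per update), parents drawn fitness-proportionally
from the update-start population, each offspring replacing a uniformly random
organism (or filling an empty slot after a cull); and per-birth mutation of
trait bits, neutral tag, and viability.  *Any* mutation founds a new genotype
and a genealogy record — the cladogenesis convention is genotypic, so most
branching is near-neutral (tag mutations at 0.05 per birth dominate), which
decouples branching from phenotypic change and produces the stemmy,
tip-heavy trees this system is known for.

Parameter defaults that the study conditions do not pin down were fixed once,
by forward calibration of the unperturbed community, to satisfy two
qualitative requirements of the system being emulated: (i) pre-event trees
carry on the order of a hundred tips and twice that many branching events at
desk scale, and (ii) the control community maintains deep coexisting
specialist clades — frequency-dependent competition for the resource cascade
keeps several specialist lineages stably coexisting, so the population's most
recent common ancestor usually sits near the start of the run and usually
survives to its end.  That requires traits to be genuinely costly
(`trait_cost = 0.5`) so that specialists rather than one sweeping generalist
occupy the cascade, and a low trait-flip rate (`mu_trait = 3e-4` per bit per
birth) so that clades keep their niche identity; the neutral-tag rate
(`mu_tag = 0.05`) then controls tree size without disturbing the ecology.
With these values a desk-scale control retains its pre-event root through the
full run in roughly nine out of ten replicates, while the disaster-taxa
response to a resource crisis (below) remains intact.

## Treatments

Five treatments share identical pre-event histories (100,000 updates at paper
scale, 10,000 at desk scale):

* **control** — no perturbation; the run continues through an alignment
  window equal to the press duration, then the recovery period.
* **pulse, strong / weak** — an instantaneous cull to 4 / 36 survivors,
  drawn uniformly from the viable organisms only; no environmental change.
  The desk profile keeps the same absolute survivor counts (1% and 9% of
  400), preserving the character of the strong cull as a near-total
  bottleneck.
* **press, strong / weak** — basal inflows multiplied by 0.01 / 0.1 for
  5,000 updates (1,000 at desk scale), then restored.  Selectivity is
  emergent: with the cascade starved, merit collapses and selection favours
  cheap, trait-poor replicators ("disaster taxa"), which drive functional
  clades extinct.

Equal absolute time is allotted to pre- and post-event evolution.  Snapshots
are taken immediately before the event, immediately after it, and at fixed
offsets into the recovery.

## From genealogy to phylogeny

A snapshot's phylogeny has one tip per genotype extant at the sampling time.
Along each genotype's timeline, the origins of its child genotypes are
candidate branching events; an event is a node only if at least two lines of
descent from it reach the sample (the genotype's own continuation counts when
it is extant or leads to extant descendants); single-survivor events collapse
into branch length.  Node ages are the origin updates of the diverging child
genotypes, so the tree is ultrametric by construction with branch lengths in
updates.  Children originating at the same update form a genuine
multifurcation rather than an arbitrarily resolved one, and an extant
ancestor becomes a tip hanging off its last retained branching event
(a zero-length tail is possible).  Child order is tie-broken
lexicographically by genotype id so serialization is reproducible.  The
pruning is verified in the test suite against a brute-force oracle that
enumerates all ancestor–descendant paths and compares the full matrix of
pairwise divergence times.

## Metrics

* **Root age** — age of the deepest branching event; the most basic record of
  deep history.  *Root retention* asks whether a later tree's root is the
  same genealogical event (same age, same host genotype) as the pre-event
  root.
* **Binned node retention** — branching ages are binned into half-open
  intervals (5,000 updates at paper scale, 1,000 at desk scale, anchored at
  update 0); later trees are pruned at the event start and each bin's count
  is divided by the pre-event reference count.  Bins empty at both times are
  excluded; scores of zero are kept (they record total loss of a bin's
  events); averages run over replicates whose reference bin was occupied,
  with two standard errors.  Because later trees cannot gain pre-cutoff
  nodes, retention is bounded by 100% and non-increasing in time.
* **Pybus–Harvey gamma** — with internode intervals `g_k` (a node of `m`
  children contributes `m - 1` simultaneous splits with zero-length
  intervals), `T = sum(k * g_k)`, `A_i = sum_{k<=i} k * g_k`,
  `gamma = (mean(A_2..A_{n-1}) - T/2) / (T * sqrt(1/(12(n-2))))`.
  Negative values mean branching concentrated rootward.  The statistic is
  undefined below three tips; such snapshots are reported missing and
  excluded from aggregates.  It is asymptotically standard normal under a
  pure birth process, which the suite checks on 500 simulated 50-tip Yule
  trees, and unit-invariant, which the suite checks by rescaling time.
* **Noncumulative stemminess (NCS)** — per internal non-root node, the stem
  branch against the immediately subtended branches.  Two variants are
  provided because descriptions of NCS in the literature differ: the bounded
  form `l_j / (l_j + sum(l_c))` in [0, 1], and an inverse-ratio form
  `sum(l_c) / l_j` which can exceed 1 (short basal stems inflate it).  The
  bounded form is the default; every pipeline output records the variant
  used.  Zero-length stems are skipped and counted, not treated as infinite.
* **Root-gap distances** — the age gaps from the root to the next two oldest
  branching events (`d1`, `d2`), with multifurcation multiplicity so a
  multifurcating root gives `d1 = 0`; missing gaps on small trees are
  reported absent.
* **Turnover** — genotype originations, extinctions and persistences over an
  interval, the demographic background of the gamma time courses.

Treatment comparisons use one-way ANOVA with Tukey-HSD pairwise tests for
retention and gamma, and Kruskal–Wallis with Tukey-type comparisons of
average ranks (the Nemenyi form, against the studentized range distribution)
for NCS, whose distribution is heavily non-normal.  Compact letter displays
are built by insert-and-absorb over the non-significance graph at
`alpha = 0.05`; treatments sharing a letter are not significantly different
after correction.  Gamma aggregates include only replicates that kept the
pre-event root, to avoid comparing trees of very different heights; NCS is
reported separately for root-keeping and root-losing replicates.

## A worked desk-scale run

```{r example, eval = FALSE}
prof <- desk_profile("press-strong")
exp <- run_experiment(prof$config, prof$schedule, seed = 1)
pre <- build_tree(exp$log, 10000, extant = unique(exp$populations[["pre"]]))
end <- build_tree(exp$log, 21000,
                  extant = unique(exp$populations[["rec10000"]]))
root_age(pre); root_age(end)
root_retained(pre, end)
pybus_harvey_gamma(pre); ncs(pre)$value
```

The full workflow lives in `analysis/01_simulate.R` through
`analysis/05_compare.R`, thin drivers over the package functions that write
their tables under `results/`.

## Problem sizes, numerical choices, and degenerate cases

Routine analyses and the test suite run the desk profile: 400 organisms,
10,000 + 1,000 + 10,000 updates, around twenty replicates per treatment, a
scale at which a replicate simulates in about a second and the qualitative
contrasts between treatments are already stable.  The paper-scale profile
(3600 organisms, 205,000 updates) is provided through the same interface for
larger runs.

Numerical conventions worth knowing: bins are half-open `[iB, (i+1)B)`
anchored at update 0; a genotype's extinction is stamped with the update
during which its last organism disappeared, so "extant at `t`" means
`origin <= t < extinction`; a pulse cull is stamped at the following update
boundary, so the pre-event snapshot still contains the victims, and the
post-cull tree is built from the survivor list explicitly.  Within an update,
parents are drawn from the update-start population, which keeps genealogy
origins strictly ordered along parent chains.  Snapshots with fewer than two
extant genotypes are degenerate: they are excluded from tree metrics and
itemized, mirroring the declining replicate counts in the aggregates.
Ultrametricity of parsed trees is enforced to a relative tolerance of 1e-6.

## What the generator does and does not emulate

The simulator reproduces the features the analyses depend on: genotype-level
genealogy with near-neutral cladogenesis, density-dependent competition for a
cross-feeding resource cascade with exactly two exogenous inflows, random
culls of viable organisms, and emergent press selectivity.  It deliberately
omits genome execution on a virtual CPU, spatial structure, recombination,
and per-instruction mutation models.  Consequently the package's simulated
magnitudes (retention percentages, gamma values, replicate fractions) are
properties of this emulator at the chosen scale, not of any particular
full-scale system; passing tests demonstrate the qualitative contrasts —
strong extinctions erode deep history and shift root ages where weak ones do
not, press events do so selectively — and the correctness of the metrics, not
numeric agreement with external runs.

## Known limitations

Desk-scale strong-press runs lose the pre-event root almost always, so the
root-retaining NCS series for that treatment is sparse; the weak-press
inflow factor is fixed at 0.1 rather than calibrated to match weak-pulse
attrition; and gamma's known insensitivity to deep structure means its
treatment differences fade over the recovery — an expected property of the
statistic, reproduced here, not a defect of the implementation.
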