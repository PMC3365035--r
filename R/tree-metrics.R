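#' Lineage-through-time series
#'
#' Extracts the branching ages of an ultrametric tree and the internode
#' intervals `g_k` during which exactly `k` lineages exist.  A node with `m`
#' children contributes its age `m - 1` times (a multifurcation is treated as
#' simultaneous splits separated by zero-length intervals), so lineage counts
#' may jump by more than one.
#'
#' @param tree A `phylo_eco`.
#' @return An object of class `ltt_series`: list with `branching_ages`
#'   (sorted, `t_2 <= ... <= t_n`), `sample_time`, `n` (tip count), and `g`
#'   (vector of internode intervals, `g[k - 1]` is `g_k` for `k = 2..n`,
#'   with `t_{n+1} = sample_time`).
#' @export
ltt <- function(tree) {
  stopifnot(inherits(tree, "phylo_eco"))
  if (tree$n_tips < 2L) stop("degenerate tree: fewer than 2 tips")
  n_children <- tabulate(tree$phylo$edge[, 1L],
                         nbins = tree$n_tips + tree$phylo$Nnode)
  mult <- n_children[(tree$n_tips + 1L):(tree$n_tips + tree$phylo$Nnode)] - 1L
  ages <- sort(rep(tree$node_ages, mult))
  make_ltt(ages, tree$sample_time)
}

#' Assemble an LTT series from branching ages
#'
#' @param branching_ages Branching ages `t_2..t_n` (any order).
#' @param sample_time The "present" of the tree.
#' @return An `ltt_series`.
#' @export
make_ltt <- function(branching_ages, sample_time) {
  ages <- sort(branching_ages)
  if (any(ages > sample_time)) stop("branching age beyond sample time")
  n <- length(ages) + 1L
  g <- diff(c(ages, sample_time))
  out <- list(branching_ages = ages, sample_time = sample_time, n = n, g = g)
  class(out) <- "ltt_series"
  out
}

#' @export
print.ltt_series <- function(x, ...) {
  cat("<ltt_series> n =", x$n, "| root age", x$branching_ages[1],
      "| sampled at", x$sample_time, "\n")
  invisible(x)
}

#' Pybus-Harvey gamma statistic
#'
#' With `T = sum(k * g_k)` and `A_i = sum_{k=2}^{i} k * g_k`,
#' \deqn{\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1} A_i - T/2}
#'                    {T \sqrt{1 / (12 (n-2))}}}
#' Negative values indicate branching events concentrated towards the root;
#' under a pure-birth process the statistic is asymptotically standard
#' normal.  Gamma is invariant to uniform rescaling of time.
#'
#' @param x An `ltt_series` or `phylo_eco`.
#' @return The gamma value.  Errors for `n < 3` (statistic undefined) and for
#'   zero total internode length.
#' @export
pybus_harvey_gamma <- function(x) {
  if (inherits(x, "phylo_eco")) x <- ltt(x)
  stopifnot(inherits(x, "ltt_series"))
  n <- x$n
  if (n < 3L) stop("gamma undefined for fewer than 3 tips")
  kg <- (2:n) * x$g
  A <- cumsum(kg)
  T_tot <- A[n - 1L]
  if (T_tot <= 0) stop("degenerate tree: zero total internode length")
  (mean(A[1:(n - 2L)]) - T_tot / 2) / (T_tot * sqrt(1 / (12 * (n - 2L))))
}

#' Noncumulative stemminess
#'
#' For each internal non-root node `j` with stem length `l_j` (branch to its
#' parent) and immediate-children branch lengths `l_c`:
#' * `rohlf1990`: `s_j = l_j / (l_j + sum(l_c))`, bounded in `[0, 1]`;
#' * `inverse-ratio`: `s'_j = sum(l_c) / l_j`, unbounded above (values below
#'   1 indicate long branches from the root; values above 1 short branches
#'   near the root).
#' The tree value is the arithmetic mean over included nodes; nodes whose
#' denominator is zero are skipped and counted.
#'
#' @param tree A `phylo_eco`.
#' @param variant "rohlf1990" (default) or "inverse-ratio".
#' @return An object of class `stemminess`: list with `value`, `variant`,
#'   `n_internal_nodes` used and `n_skipped`.  Errors when the tree has no
#'   internal non-root node or all nodes are skipped.
#' @export
ncs <- function(tree, variant = c("rohlf1990", "inverse-ratio")) {
  stopifnot(inherits(tree, "phylo_eco"))
  variant <- match.arg(variant)
  phy <- tree$phylo
  n_tip <- tree$n_tips
  internal <- (n_tip + 1L):(n_tip + phy$Nnode)
  nonroot <- internal[internal != n_tip + 1L]
  if (!length(nonroot)) stop("no internal non-root node: stemminess undefined")
  vals <- numeric(0)
  skipped <- 0L
  for (v in nonroot) {
    lj <- phy$edge.length[phy$edge[, 2L] == v]
    lc <- sum(phy$edge.length[phy$edge[, 1L] == v])
    if (variant == "rohlf1990") {
      if (lj + lc <= 0) { skipped <- skipped + 1L; next }
      vals <- c(vals, lj / (lj + lc))
    } else {
      if (lj <= 0) { skipped <- skipped + 1L; next }
      vals <- c(vals, lc / lj)
    }
  }
  if (!length(vals)) stop("all internal nodes skipped: stemminess undefined")
  out <- list(value = mean(vals), variant = variant,
              n_internal_nodes = length(vals), n_skipped = skipped)
  class(out) <- "stemminess"
  out
}

#' @export
print.stemminess <- function(x, ...) {
  cat("<stemminess>", x$variant, "=", signif(x$value, 6),
      "over", x$n_internal_nodes, "nodes",
      if (x$n_skipped) paste0("(", x$n_skipped, " skipped)") else "", "\n")
  invisible(x)
}

#' Root age of a tree
#'
#' Age (in updates since the time origin) of the deepest branching node, the
#' most recent common ancestor of all sampled genotypes.
#'
#' @param tree A `phylo_eco`.
#' @return The root age in updates.
#' @export
root_age <- function(tree) {
  stopifnot(inherits(tree, "phylo_eco"))
  tree$root_age
}

#' Distances from the root to the next two oldest nodes
#'
#' `d1` is the age difference between the oldest non-root branching event and
#' the root; `d2` likewise for the second oldest.  Branching events carry
#' multifurcation multiplicity, so a multifurcating root yields `d1 = 0`
#' (a co-occurring split sits at distance zero).  Missing distances (trees
#' with too few branching events) are `NA`.
#'
#' @param tree A `phylo_eco`.
#' @return Named numeric vector `c(d1 = , d2 = )`.
#' @export
root_gap_distances <- function(tree) {
  ages <- ltt(tree)$branching_ages
  c(d1 = if (length(ages) >= 2L) ages[2L] - ages[1L] else NA_real_,
    d2 = if (length(ages) >= 3L) ages[3L] - ages[1L] else NA_real_)
}

#' Simulate a pure-birth (Yule) LTT series
#'
#' Simple independent birth process used for gamma calibration: with `k`
#' lineages the waiting time to the next branching is exponential with rate
#' `k * lambda`.  Conditioned on `n` tips the gamma statistic of such trees
#' is asymptotically standard normal.
#'
#' @param n Number of tips.
#' @param lambda Per-lineage birth rate.
#' @return An `ltt_series`.
#' @export
yule_ltt <- function(n, lambda = 1) {
  stopifnot(n >= 3L, lambda > 0)
  g <- stats::rexp(n - 1L, rate = (2:n) * lambda)
  ages <- cumsum(c(0, g[-(n - 1L)]))
  make_ltt(ages, sum(g[n - 1L], ages[n - 1L]))
}
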