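#' Build the phylogeny of extant genotypes
#'
#' Prunes a genotype genealogy down to the ultrametric "molecular" phylogeny
#' of the genotypes extant at `sample_time`.  Along each genotype's timeline,
#' the origins of its child genotypes are potential branching events; an event
#' becomes an internal node only when at least two lines of descent from that
#' point survive to the sample (counting the genotype's own continuation when
#' it is extant or leads to extant descendants).  Events with a single
#' surviving line are collapsed into branch length.  An extant genotype that
#' also has extant descendants appears as a tip hanging off its last retained
#' branching event.  Children that originate at the same update form a
#' genuine multifurcation.
#'
#' @param log A genealogy log data frame (see [genealogy_log()]).
#' @param sample_time Sampling time in updates; tips all sit at this age.
#' @param extant Optional explicit vector of extant genotype ids (defaults to
#'   [extant_genotypes()] of the log at `sample_time`; an explicit set is
#'   needed e.g. immediately after a pulse cull, when survivors and victims
#'   share the cull update).
#' @return An object of class `phylo_eco`: list with `phylo` (an
#'   [ape::read.tree()]-style tree with branch lengths in updates and genotype
#'   ids as tip labels), `sample_time`, `root_age`, `n_tips`, `node_ages`
#'   (per internal node, in `phylo` node order), `node_hosts` (genotype id on
#'   whose timeline each internal node sits, `NA` when unknown), and
#'   `root_host`.
#' @export
build_tree <- function(log, sample_time, extant = NULL) {
  if (is.null(extant)) extant <- extant_genotypes(log, sample_time)
  extant <- as.character(extant)
  if (length(extant) < 2L)
    stop("degenerate tree: fewer than 2 genotypes extant at ", sample_time)

  log <- log[log$origin_update <= sample_time, , drop = FALSE]
  ids <- as.character(log$genotype_id)
  n <- length(ids)
  pidx <- match(as.character(log$parent_id), ids)  # NA for founder
  origin <- log$origin_update
  in_extant <- ids %in% extant
  if (!all(extant %in% ids)) stop("extant ids missing from genealogy log")
  has_par <- !is.na(pidx)
  if (any(origin[has_par] <= origin[pidx[has_par]]))
    stop("genealogy violates strict parent-before-child origin ordering")

  # survival: extant self or any surviving child; children originate strictly
  # after parents, so one origin-descending sweep suffices
  surv <- in_extant
  ord <- order(origin, decreasing = TRUE)
  for (i in ord) {
    if (surv[i] && !is.na(pidx[i])) surv[pidx[i]] <- TRUE
  }

  # per surviving genotype: surviving children grouped by origin time
  sidx <- which(surv)
  child_of <- split(sidx[!is.na(pidx[sidx])],
                    pidx[sidx][!is.na(pidx[sidx])])

  # growing node arrays; handles are node indices
  node_age <- numeric(0)
  node_host <- character(0)
  node_tip <- logical(0)
  node_children <- list()
  node_key <- character(0)   # lexicographic sort key: min tip label in subtree
  add_node <- function(age, host, tip, children, key) {
    node_age[length(node_age) + 1L] <<- age
    node_host[length(node_host) + 1L] <<- host
    node_tip[length(node_tip) + 1L] <<- tip
    node_children[[length(node_children) + 1L]] <<- children
    node_key[length(node_key) + 1L] <<- key
    length(node_age)
  }

  handle <- integer(n)
  for (i in ord) {               # children before parents
    if (!surv[i]) next
    chain <- 0L
    if (in_extant[i])
      chain <- add_node(sample_time, ids[i], TRUE, integer(0), ids[i])
    kids <- child_of[[as.character(i)]]
    if (!is.null(kids)) {
      for (tc in sort(unique(origin[kids]), decreasing = TRUE)) {
        grp <- handle[kids[origin[kids] == tc]]
        if (chain != 0L || length(grp) >= 2L) {
          members <- c(grp, if (chain != 0L) chain)
          members <- members[order(node_key[members], method = "radix")]
          chain <- add_node(tc, ids[i], FALSE, members,
                            min(node_key[members]))
        } else {
          chain <- grp
        }
      }
    }
    handle[i] <- chain
  }

  root <- handle[which(is.na(pidx))[1]]
  if (node_tip[root])
    stop("degenerate tree: a single line of descent at ", sample_time)

  phylo_eco_from_nodes(node_age, node_host, node_tip, node_children, root,
                       sample_time)
}

# assemble an ape "phylo" from the node arrays (preorder traversal)
phylo_eco_from_nodes <- function(node_age, node_host, node_tip, node_children,
                                 root, sample_time) {
  n_tip <- sum(node_tip)
  n_int <- length(node_age) - n_tip
  ape_id <- integer(length(node_age))
  tip_label <- character(n_tip)
  int_age <- numeric(n_int)
  int_host <- character(n_int)
  edges <- matrix(0L, length(node_age) - 1L, 2L)
  elen <- numeric(nrow(edges))

  next_tip <- 0L; next_int <- 0L; next_edge <- 0L
  stack <- root
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (node_tip[nd]) {
      next_tip <- next_tip + 1L
      ape_id[nd] <- next_tip
      tip_label[next_tip] <- node_host[nd]
    } else {
      next_int <- next_int + 1L
      ape_id[nd] <- n_tip + next_int
      int_age[next_int] <- node_age[nd]
      int_host[next_int] <- node_host[nd]
      # push children in reverse so they pop in stored order
      stack <- c(stack, rev(node_children[[nd]]))
    }
  }
  # second pass for edges (parents already numbered)
  stack <- root
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (node_tip[nd]) next
    for (ch in node_children[[nd]]) {
      next_edge <- next_edge + 1L
      edges[next_edge, ] <- c(ape_id[nd], ape_id[ch])
      elen[next_edge] <- node_age[ch] - node_age[nd]
      stack <- c(stack, ch)
    }
  }

  phy <- structure(list(edge = edges, edge.length = elen,
                        Nnode = n_int, tip.label = tip_label),
                   class = "phylo", order = "cladewise")
  root_age <- int_age[1L]
  phy$root.edge <- root_age

  out <- list(phylo = phy, sample_time = sample_time, root_age = root_age,
              n_tips = n_tip, node_ages = int_age, node_hosts = int_host,
              root_host = int_host[1L], tip_genotypes = tip_label)
  class(out) <- "phylo_eco"
  out
}

#' @export
print.phylo_eco <- function(x, ...) {
  cat("<phylo_eco>", x$n_tips, "tips,", length(x$node_ages),
      "internal nodes | root age", x$root_age,
      "| sampled at", x$sample_time, "\n")
  invisible(x)
}

#' Serialize / parse trees as newick
#'
#' `to_newick` writes the tree with branch lengths in updates, genotype ids
#' as tip labels, and the root age as a root edge.  `from_newick` parses such
#' a string, recovering node ages by summing stem lengths from the root, and
#' rejects trees whose tips are not co-temporal within
#' `tol * sample_time` (all downstream metrics assume ultrametry).
#'
#' @param tree A `phylo_eco`.
#' @param text A newick string with branch lengths.
#' @param tol Relative ultrametricity tolerance (default 1e-6).
#' @return `to_newick` a string; `from_newick` a `phylo_eco` (node hosts
#'   unknown, `NA`).
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo_eco"))
  ape::write.tree(tree$phylo)
}

#' @rdname to_newick
#' @export
from_newick <- function(text, tol = 1e-6) {
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("newick parse failure")
  if (is.null(phy$edge.length)) stop("newick input lacks branch lengths")
  root_edge <- if (is.null(phy$root.edge)) 0 else phy$root.edge
  n_tip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)     # distance from root
  tip_depth <- depth[seq_len(n_tip)]
  sample_time <- root_edge + max(tip_depth)
  if (diff(range(tip_depth)) > tol * max(sample_time, 1))
    stop("non-ultrametric input: tip depths differ by ",
         signif(diff(range(tip_depth)), 4))
  int_age <- root_edge + depth[(n_tip + 1L):(n_tip + phy$Nnode)]
  out <- list(phylo = phy, sample_time = sample_time,
              root_age = int_age[1L], n_tips = n_tip,
              node_ages = int_age,
              node_hosts = rep(NA_character_, phy$Nnode),
              root_host = NA_character_,
              tip_genotypes = phy$tip.label)
  class(out) <- "phylo_eco"
  out
}

#' Discard node ages after a cutoff
#'
#' Retains only node ages at or before `cutoff` (typically the beginning of
#' the extinction event), so that later trees are compared against the
#' pre-extinction tree on common temporal support.
#'
#' @param ages Numeric vector of node ages.
#' @param cutoff Cutoff in updates.
#' @return The ages `<= cutoff`, sorted.
#' @export
prune_nodes_after <- function(ages, cutoff) {
  sort(ages[ages <= cutoff])
}
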