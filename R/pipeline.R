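#' Experiment manifest
#'
#' Declarative description of a batch of experiments: which treatments, how
#' many replicates, the base seed, the study profile and the retention bin
#' width.  Replicate seeds are derived by xor-ing the replicate index (offset
#' by a per-treatment stride) into the base seed, so any replicate can be
#' regenerated in isolation.
#'
#' @param treatments Character vector among "control", "pulse-strong",
#'   "pulse-weak", "press-strong", "press-weak".
#' @param n_replicates Replicates per treatment.
#' @param base_seed Integer base seed.
#' @param profile "desk" (400 organisms, 10,000 + 1,000 + 10,000 updates) or
#'   "paper" (3600 organisms, 100,000 + 5,000 + 100,000 updates).
#' @param bin_width Node-age bin width in updates; defaults to 5000 for the
#'   paper profile and 1000 for the desk profile (a tenth of the pre-event
#'   span in both cases).
#' @param ncs_variant Stemminess variant recorded in the metric table.
#' @param out_dir Optional directory; when given, [run_pipeline()] writes its
#'   tables there as TSV.
#' @return An object of class `experiment_manifest`.
#' @export
experiment_manifest <- function(treatments = c("control", "pulse-strong",
                                               "pulse-weak", "press-strong",
                                               "press-weak"),
                                n_replicates = 20L,
                                base_seed = 1L,
                                profile = c("desk", "paper"),
                                bin_width = NULL,
                                ncs_variant = c("rohlf1990", "inverse-ratio"),
                                out_dir = NULL) {
  profile <- match.arg(profile)
  ncs_variant <- match.arg(ncs_variant)
  known <- c("control", "pulse-strong", "pulse-weak", "press-strong",
             "press-weak")
  if (!all(treatments %in% known))
    stop("unknown treatment(s): ",
         paste(setdiff(treatments, known), collapse = ", "))
  if (is.null(bin_width))
    bin_width <- if (profile == "paper") 5000 else 1000
  out <- list(treatments = treatments,
              n_replicates = as.integer(n_replicates),
              base_seed = as.integer(base_seed),
              profile = profile, bin_width = bin_width,
              ncs_variant = ncs_variant, out_dir = out_dir)
  class(out) <- "experiment_manifest"
  out
}

#' Seed for one replicate
#' @param manifest An `experiment_manifest`.
#' @param treatment Treatment label.
#' @param replicate Replicate index (1-based).
#' @return Integer seed below 2^31.
#' @export
replicate_seed <- function(manifest, treatment, replicate) {
  tix <- match(treatment, manifest$treatments)
  bitwXor(manifest$base_seed, as.integer(replicate) + 4096L * (tix - 1L))
}

#' Run the full analysis pipeline
#'
#' For every treatment x replicate: simulate the experiment, build the
#' phylogeny of extant genotypes at the immediate pre-event snapshot and at
#' every sampling offset, compute per-snapshot tree metrics (tip count, root
#' age, root-gap distances, Pybus-Harvey gamma, noncumulative stemminess in
#' both variants, root retention against the pre-event tree), and compute
#' per-bin percent retention of branching nodes against the pre-event tree
#' with the cutoff at the event start.  Treatment comparisons are then run
#' per snapshot: ANOVA/Tukey on gamma restricted to root-retaining
#' replicates, and Kruskal-Wallis/Tukey on stemminess separately for
#' root-retaining and root-losing replicates.  Failed replicates and
#' degenerate trees are excluded from aggregates and itemized.
#'
#' @param manifest An `experiment_manifest`.
#' @return List with `metrics` (per treatment, replicate, snapshot),
#'   `retention` (per-replicate per-bin), `retention_summary` (per treatment,
#'   post-event snapshot), `root_ages`, `gamma_comparisons`,
#'   `ncs_comparisons`, `failures`, `manifest`.  Written as TSVs under
#'   `manifest$out_dir` when set.
#' @export
run_pipeline <- function(manifest) {
  stopifnot(inherits(manifest, "experiment_manifest"))
  profile_fun <- if (manifest$profile == "paper") paper_profile else desk_profile

  metrics <- list(); retention <- list(); failures <- list()
  for (tr in manifest$treatments) {
    prof <- profile_fun(tr)
    cutoff <- prof$schedule$pre_updates
    for (r in seq_len(manifest$n_replicates)) {
      seed <- replicate_seed(manifest, tr, r)
      exp <- run_experiment(prof$config, prof$schedule, seed = seed)
      if (exp$failed) {
        failures[[length(failures) + 1L]] <-
          data.frame(treatment = tr, replicate = r, seed = seed,
                     reason = "population failure")
        next
      }
      res <- analyze_replicate(exp, cutoff, manifest$bin_width)
      res$metrics$treatment <- tr; res$metrics$replicate <- r
      metrics[[length(metrics) + 1L]] <- res$metrics
      if (!is.null(res$retention)) {
        res$retention$treatment <- tr; res$retention$replicate <- r
        retention[[length(retention) + 1L]] <- res$retention
      } else {
        failures[[length(failures) + 1L]] <-
          data.frame(treatment = tr, replicate = r, seed = seed,
                     reason = "degenerate pre-event tree")
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  retention <- if (length(retention)) do.call(rbind, retention) else NULL
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(treatment = character(0), replicate = integer(0),
               seed = integer(0), reason = character(0))

  retention_summary <- summarize_retention(retention, manifest$treatments)
  root_ages <- metrics[!is.na(metrics$root_age),
                       c("treatment", "replicate", "snapshot", "update",
                         "root_age")]

  gamma_comparisons <- compare_by_snapshot(
    metrics[metrics$root_retained %in% TRUE & !is.na(metrics$gamma), ],
    "gamma", anova_tukey)
  ncs_col <- if (manifest$ncs_variant == "rohlf1990") "ncs_rohlf" else
    "ncs_inverse"
  ncs_comparisons <- list(
    root_retained = compare_by_snapshot(
      metrics[metrics$root_retained %in% TRUE & !is.na(metrics[[ncs_col]]), ],
      ncs_col, kruskal_tukey),
    root_lost = compare_by_snapshot(
      metrics[metrics$root_retained %in% FALSE & !is.na(metrics[[ncs_col]]), ],
      ncs_col, kruskal_tukey))

  out <- list(metrics = metrics, retention = retention,
              retention_summary = retention_summary, root_ages = root_ages,
              gamma_comparisons = gamma_comparisons,
              ncs_comparisons = ncs_comparisons,
              failures = failures, manifest = manifest)
  if (!is.null(manifest$out_dir)) write_pipeline_tables(out)
  out
}

# per-replicate snapshot metrics + retention vs pre-event reference
analyze_replicate <- function(exp, cutoff, bin_width) {
  snaps <- exp$snapshots
  trees <- vector("list", nrow(snaps))
  for (i in seq_len(nrow(snaps))) {
    ids <- unique(exp$populations[[snaps$label[i]]])
    trees[[i]] <- tryCatch(
      build_tree(exp$log, snaps$update[i], extant = ids),
      error = function(e) NULL)
  }
  names(trees) <- snaps$label
  pre_tree <- trees[["pre"]]

  rows <- lapply(seq_len(nrow(snaps)), function(i) {
    tree <- trees[[i]]
    if (is.null(tree))
      return(data.frame(snapshot = snaps$label[i], update = snaps$update[i],
                        n_tips = NA_integer_, root_age = NA_real_,
                        d1 = NA_real_, d2 = NA_real_, gamma = NA_real_,
                        ncs_rohlf = NA_real_, ncs_inverse = NA_real_,
                        root_retained = NA))
    gaps <- root_gap_distances(tree)
    data.frame(
      snapshot = snaps$label[i], update = snaps$update[i],
      n_tips = tree$n_tips, root_age = root_age(tree),
      d1 = gaps[["d1"]], d2 = gaps[["d2"]],
      gamma = tryCatch(pybus_harvey_gamma(tree), error = function(e) NA_real_),
      ncs_rohlf = tryCatch(ncs(tree, "rohlf1990")$value,
                           error = function(e) NA_real_),
      ncs_inverse = tryCatch(ncs(tree, "inverse-ratio")$value,
                             error = function(e) NA_real_),
      root_retained = if (is.null(pre_tree)) NA else
        root_retained(pre_tree, tree))
  })
  metrics <- do.call(rbind, rows)

  ret <- NULL
  if (!is.null(pre_tree)) {
    pre_binned <- bin_node_ages(ltt(pre_tree)$branching_ages, bin_width)
    ret_rows <- list()
    for (lab in setdiff(snaps$label, "pre")) {
      tree <- trees[[lab]]
      ages <- if (is.null(tree)) numeric(0) else
        prune_nodes_after(ltt(tree)$branching_ages, cutoff)
      tb <- percent_retention(pre_binned, bin_node_ages(ages, bin_width))
      tb$snapshot <- lab
      ret_rows[[lab]] <- tb
    }
    ret <- do.call(rbind, ret_rows)
    rownames(ret) <- NULL
  }
  list(metrics = metrics, retention = ret)
}

summarize_retention <- function(retention, treatments) {
  if (is.null(retention)) return(NULL)
  out <- list()
  for (tr in treatments) {
    sub <- retention[retention$treatment == tr &
                       retention$snapshot == "post", ]
    if (!nrow(sub)) next
    tables <- split(sub, sub$replicate)
    if (length(tables) < 2L) next
    agg <- aggregate_retention(tables)
    agg$treatment <- tr
    out[[tr]] <- agg
  }
  if (length(out)) do.call(rbind, out) else NULL
}

compare_by_snapshot <- function(metrics, column, test_fun, min_per_group = 2L) {
  if (is.null(metrics) || !nrow(metrics)) return(list())
  out <- list()
  for (lab in unique(metrics$snapshot)) {
    sub <- metrics[metrics$snapshot == lab, ]
    groups <- split(sub[[column]], sub$treatment)
    groups <- groups[lengths(groups) >= min_per_group]
    if (length(groups) < 2L) next
    out[[lab]] <- test_fun(groups)
  }
  out
}

#' Mean retention in the deepest bins
#'
#' Per-replicate summary used for treatment comparisons of deep history:
#' the mean percent retention over the oldest `fraction` of the binned
#' pre-event span (bins with an occupied pre-event reference only; zeros
#' included).
#'
#' @param ret_table A per-replicate retention table from [percent_retention()]
#'   (or the pipeline's `retention` rows for one replicate and snapshot).
#' @param cutoff The pre-event cutoff in updates.
#' @param fraction Fraction of the span counted as "deep" (default 1/3).
#' @return Mean retention percent, or `NA` if no deep bin has reference
#'   nodes.
#' @export
deep_bin_retention <- function(ret_table, cutoff, fraction = 1 / 3) {
  deep <- ret_table[ret_table$bin_upper <= cutoff * fraction, ]
  vals <- deep$retention[!is.na(deep$retention)]
  if (!length(vals)) NA_real_ else mean(vals)
}

write_pipeline_tables <- function(res) {
  dir.create(res$manifest$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df))
      utils::write.table(df, file.path(res$manifest$out_dir, name),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(res$metrics, "metrics.tsv")
  wr(res$retention, "retention.tsv")
  wr(res$retention_summary, "retention_summary.tsv")
  wr(res$root_ages, "root_ages.tsv")
  wr(res$failures, "failures.tsv")
  wr(comparisons_table(res), "comparisons.tsv")
  invisible(res$manifest$out_dir)
}

#' Flatten pipeline comparisons into one table
#' @param res A [run_pipeline()] result.
#' @return Data frame with test, snapshot, group, letters, omnibus p.
#' @export
comparisons_table <- function(res) {
  rows <- list()
  harvest <- function(cmps, label) {
    for (lab in names(cmps)) {
      cm <- cmps[[lab]]
      rows[[length(rows) + 1L]] <<- data.frame(
        test = label, snapshot = lab, group = names(cm$letters),
        letters = unname(cm$letters), omnibus_p = cm$p_value)
    }
  }
  harvest(res$gamma_comparisons, "gamma_anova_tukey")
  harvest(res$ncs_comparisons$root_retained, "ncs_kruskal_root_retained")
  harvest(res$ncs_comparisons$root_lost, "ncs_kruskal_root_lost")
  if (length(rows)) do.call(rbind, rows) else
    data.frame(test = character(0), snapshot = character(0),
               group = character(0), letters = character(0),
               omnibus_p = numeric(0))
}
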