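#' Bin node ages temporally
#'
#' Counts branching-node ages in half-open bins `[i*B, (i+1)*B)` anchored at
#' update 0.
#'
#' @param ages Numeric vector of node ages (updates, >= 0).
#' @param bin_width Bin width `B` in updates (default 5000).
#' @return An object of class `binned_ages`: list with `bin_width` and
#'   `counts` (integer vector over bins `0..max`, named by bin index).
#' @export
bin_node_ages <- function(ages, bin_width = 5000) {
  stopifnot(bin_width > 0, all(ages >= 0))
  idx <- floor(ages / bin_width)
  n_bins <- if (length(idx)) max(idx) + 1L else 0L
  counts <- tabulate(idx + 1L, nbins = n_bins)
  names(counts) <- as.character(seq_len(n_bins) - 1L)
  out <- list(bin_width = bin_width, counts = counts)
  class(out) <- "binned_ages"
  out
}

#' Per-bin percent retention of branching nodes
#'
#' Compares a later (post-event, pruned at the pre-event cutoff) set of
#' binned node ages against the immediate pre-event reference.  Per bin:
#' empty in both -> excluded; otherwise `100 * post / pre`.  A bin empty
#' before the event but occupied after it violates the subset invariant
#' (later trees cannot gain pre-cutoff nodes) and raises an error.
#'
#' @param pre,post `binned_ages` with identical bin width; `post` must come
#'   from ages pruned at the pre-event cutoff (see [prune_nodes_after()]).
#' @return A data frame with columns `bin`, `bin_lower`, `bin_upper`, `pre`,
#'   `post`, `retention` (percent, `NA` when excluded), `excluded`.
#' @export
percent_retention <- function(pre, post) {
  stopifnot(inherits(pre, "binned_ages"), inherits(post, "binned_ages"))
  if (pre$bin_width != post$bin_width)
    stop("mismatched bin widths: ", pre$bin_width, " vs ", post$bin_width)
  n <- max(length(pre$counts), length(post$counts))
  pad <- function(x) { length(x) <- n; x[is.na(x)] <- 0L; x }
  p <- pad(pre$counts); q <- pad(post$counts)
  if (any(p == 0L & q > 0L))
    stop("subset violation: bin occupied after the event but empty before it")
  retention <- ifelse(p > 0L, 100 * q / p, NA_real_)
  data.frame(
    bin = seq_len(n) - 1L,
    bin_lower = (seq_len(n) - 1L) * pre$bin_width,
    bin_upper = seq_len(n) * pre$bin_width,
    pre = p, post = q,
    retention = retention,
    excluded = p == 0L & q == 0L
  )
}

#' Aggregate retention across replicates
#'
#' Per bin, averages percent retention over the replicates whose pre-event
#' bin held at least one node; zeros are included (they record total loss of
#' that bin's branching events).  Bins empty in every replicate's reference
#' are dropped.
#'
#' @param tables List of per-replicate data frames from
#'   [percent_retention()] (same bin width).
#' @return A data frame with `bin`, `bin_lower`, `bin_upper`, `mean`
#'   (percent), `two_se` (twice the standard error; `NA` with a single
#'   replicate), and `n_replicates` used per bin.
#' @export
aggregate_retention <- function(tables) {
  stopifnot(length(tables) >= 2L)
  all_bins <- sort(unique(unlist(lapply(tables, `[[`, "bin"))))
  rows <- lapply(all_bins, function(b) {
    vals <- unlist(lapply(tables, function(tb) {
      r <- tb$retention[tb$bin == b]
      r[!is.na(r)]
    }))
    if (!length(vals)) return(NULL)
    width <- tables[[1]]$bin_upper[1] - tables[[1]]$bin_lower[1]
    data.frame(bin = b, bin_lower = b * width, bin_upper = (b + 1) * width,
               mean = mean(vals),
               two_se = if (length(vals) > 1)
                 2 * stats::sd(vals) / sqrt(length(vals)) else NA_real_,
               n_replicates = length(vals))
  })
  do.call(rbind, rows)
}

#' Is the pre-event phylogenetic root retained?
#'
#' TRUE iff the later tree's root corresponds to the same genealogical
#' branching event as the pre-event tree's root, matched by root age and by
#' the genotype on whose timeline the branching occurred.  When host
#' genotypes are unavailable (trees parsed from newick) the match falls back
#' to root age alone.
#'
#' @param pre_tree,post_tree `phylo_eco` trees from the same replicate.
#' @return Logical flag.
#' @export
root_retained <- function(pre_tree, post_tree) {
  stopifnot(inherits(pre_tree, "phylo_eco"), inherits(post_tree, "phylo_eco"))
  same_age <- isTRUE(all.equal(pre_tree$root_age, post_tree$root_age))
  if (is.na(pre_tree$root_host) || is.na(post_tree$root_host))
    return(same_age)
  same_age && identical(pre_tree$root_host, post_tree$root_host)
}

#' Root-age histograms across replicates
#'
#' Bins replicate root ages per time point, and reports per time point the
#' fraction of replicates with a root younger than `young_cutoff` updates as
#' well as the fractions whose root originated during and after the event
#' window.
#'
#' @param data Data frame with columns `timepoint` and `root_age` (one row
#'   per replicate and time point).
#' @param bin_width Histogram bin width in updates.
#' @param event_window Optional `c(start, end)` of the extinction event.
#' @param young_cutoff Age below which a root counts as "old history intact"
#'   (default 5000 updates).
#' @return List with `counts` (timepoint, bin_lower, bin_upper, count) and
#'   `fractions` (timepoint, n, frac_young, frac_during_event,
#'   frac_after_event; the event fractions are `NA` without an event window).
#' @export
root_age_histogram <- function(data, bin_width = 5000, event_window = NULL,
                               young_cutoff = 5000) {
  stopifnot(bin_width > 0)
  if (!nrow(data))
    return(list(counts = data.frame(timepoint = character(0),
                                    bin_lower = numeric(0),
                                    bin_upper = numeric(0),
                                    count = integer(0)),
                fractions = data.frame(timepoint = character(0),
                                       n = integer(0),
                                       frac_young = numeric(0),
                                       frac_during_event = numeric(0),
                                       frac_after_event = numeric(0))))
  counts <- do.call(rbind, lapply(split(data, data$timepoint), function(d) {
    idx <- floor(d$root_age / bin_width)
    tab <- table(idx)
    data.frame(timepoint = d$timepoint[1],
               bin_lower = as.numeric(names(tab)) * bin_width,
               bin_upper = (as.numeric(names(tab)) + 1) * bin_width,
               count = as.integer(tab))
  }))
  fractions <- do.call(rbind, lapply(split(data, data$timepoint), function(d) {
    data.frame(
      timepoint = d$timepoint[1],
      n = nrow(d),
      frac_young = mean(d$root_age < young_cutoff),
      frac_during_event = if (is.null(event_window)) NA_real_ else
        mean(d$root_age >= event_window[1] & d$root_age <= event_window[2]),
      frac_after_event = if (is.null(event_window)) NA_real_ else
        mean(d$root_age > event_window[2])
    )
  }))
  rownames(counts) <- rownames(fractions) <- NULL
  list(counts = counts, fractions = fractions)
}

#' Genotype turnover over an interval
#'
#' @param log A genealogy log data frame.
#' @param interval `c(t0, t1)` with `t0 < t1`; originations and extinctions
#'   are counted in `[t0, t1)`, persistences are genotypes extant throughout.
#' @return Named integer vector `c(originations, extinctions, persistences)`.
#' @export
turnover_counts <- function(log, interval) {
  t0 <- interval[1]; t1 <- interval[2]
  if (!(t0 < t1)) stop("interval must satisfy t0 < t1")
  orig <- sum(log$origin_update >= t0 & log$origin_update < t1)
  ext <- sum(!is.na(log$extinction_update) &
               log$extinction_update >= t0 & log$extinction_update < t1)
  persist <- sum(log$origin_update <= t0 &
                   (is.na(log$extinction_update) | log$extinction_update >= t1))
  c(originations = as.integer(orig), extinctions = as.integer(ext),
    persistences = as.integer(persist))
}
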