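#' Initial ecology state
#'
#' Builds the starting state: a population of `population_size` copies of a
#' founder genotype with no traits and neutral tag 0, and resources at their
#' organism-free equilibrium `inflow / decay` unless supplied.
#'
#' @param cfg An `ecology_config`.
#' @param resources Optional starting concentrations (defaults to
#'   `inflow / decay`).
#' @return An object of class `eco_state`.
#' @export
init_ecology_state <- function(cfg, resources = NULL) {
  if (is.null(resources)) resources <- cfg$inflow / cfg$decay
  stopifnot(length(resources) == cfg$n_functions, all(resources >= 0))
  state <- list(
    organisms = rep(1L, cfg$population_size),
    resources = as.numeric(resources),
    update = 0L,
    next_tag = 1L,
    genealogy = list(
      parent = 0L, origin = 0L, extinct = -1L, traits = 0L, tag = 0L,
      viable = 1L, count = cfg$population_size, ntraits = 0L
    ),
    failed = FALSE
  )
  class(state) <- "eco_state"
  state
}

#' Advance the ecology
#'
#' Runs `n_updates` updates of resource dynamics, consumption, fitness-
#' proportional birth and mutation (see the package vignette for the update
#' cycle).  All randomness comes from R's RNG, so runs are reproducible under
#' `set.seed()`.
#'
#' @param state An `eco_state`.
#' @param cfg An `ecology_config`; its `inflow` is the inflow in force for
#'   these updates (use [set_press_inflows()] during a press window).
#' @param n_updates Number of updates to run.
#' @param capture_at Absolute update times at which to snapshot the organism
#'   genotype-id vector.
#' @return The advanced `eco_state`; any requested snapshots are in
#'   `attr(state, "captures")` (list of integer vectors) with times in
#'   `attr(state, "capture_update")`.
#' @export
step_update <- function(state, cfg, n_updates = 1L, capture_at = integer(0)) {
  stopifnot(inherits(state, "eco_state"), inherits(cfg, "ecology_config"))
  out <- sim_steps_cpp(unclass(state), as.integer(n_updates),
                       cfg$inflow, unclass(cfg), as.integer(capture_at))
  new <- list(
    organisms = out$organisms,
    resources = out$resources,
    update = out$update,
    next_tag = out$next_tag,
    genealogy = out$genealogy,
    failed = state$failed || out$failed
  )
  class(new) <- "eco_state"
  attr(new, "captures") <- out$captures
  attr(new, "capture_update") <- out$capture_update
  new
}

#' Instantaneous pulse cull
#'
#' Keeps exactly `survivors_k` organisms, drawn uniformly without replacement
#' from the viable organisms only; resources and configuration are untouched
#' and the population refills in subsequent updates through births.  Genotypes
#' whose last organism is removed are stamped extinct at the current update
#' boundary (they were extant through the pre-cull snapshot).
#'
#' @param state An `eco_state`.
#' @param survivors_k Number of organisms kept (>= 2).
#' @return The culled `eco_state`.
#' @export
apply_pulse_cull <- function(state, survivors_k) {
  stopifnot(inherits(state, "eco_state"))
  survivors_k <- as.integer(survivors_k)
  if (survivors_k < 2L) stop("survivors_k must be at least 2")
  viable_idx <- which(state$genealogy$viable[state$organisms] == 1L)
  if (length(viable_idx) < survivors_k)
    stop("fewer viable organisms (", length(viable_idx),
         ") than requested survivors (", survivors_k, "): replicate unrecoverable")
  keep <- if (length(viable_idx) == survivors_k) viable_idx else
    sample(viable_idx, survivors_k)
  removed <- state$organisms[-keep]
  state$organisms <- state$organisms[sort(keep)]
  if (length(removed)) {
    lost <- tabulate(removed, nbins = length(state$genealogy$count))
    state$genealogy$count <- state$genealogy$count - lost
    gone <- state$genealogy$count == 0L & state$genealogy$extinct == -1L
    state$genealogy$extinct[gone] <- state$update + 1L
  }
  state
}

#' Run one full experiment
#'
#' Executes a treatment schedule: `pre_updates` of unperturbed evolution, the
#' event (instantaneous cull for a pulse; a window of reduced basal inflows
#' for a press; an unaltered window of the same length for the control), then
#' `recovery_updates` more.  Snapshots are captured immediately before the
#' event ("pre"), immediately after it ("post", sampling offset 0) and at each
#' later sampling offset into the recovery.  Identical `cfg`, `sched` and
#' `seed` give identical results.
#'
#' @param cfg An `ecology_config`.
#' @param sched A `treatment_schedule`.
#' @param seed Integer seed for the replicate.
#' @return An object of class `eco_experiment`: list with `log` (genealogy
#'   data frame, see [genealogy_log()]), `snapshots` (data frame of label and
#'   update), `populations` (named list of organism genotype-id vectors, one
#'   per snapshot), `config`, `schedule`, `seed`, and `failed`.
#' @export
run_experiment <- function(cfg, sched, seed = 1L) {
  stopifnot(inherits(cfg, "ecology_config"), inherits(sched, "treatment_schedule"))
  validate_treatment_schedule(sched)
  set.seed(as.integer(seed))
  state <- init_ecology_state(cfg)

  pops <- list()
  snap_update <- integer(0)

  # pre-event phase, capturing the immediate pre-event point
  state <- step_update(state, cfg, sched$pre_updates, capture_at = sched$pre_updates)
  pops[["pre"]] <- attr(state, "captures")[[1]]
  snap_update["pre"] <- sched$pre_updates

  # event
  if (sched$kind == "pulse") {
    if (!state$failed) {
      culled <- tryCatch(apply_pulse_cull(state, sched$pulse_survivors),
                         error = function(e) NULL)
      if (is.null(culled)) state$failed <- TRUE else state <- culled
    }
    event_end <- sched$pre_updates
    pops[["post"]] <- state$organisms
    snap_update["post"] <- event_end
  } else {
    event_cfg <- if (sched$kind == "press")
      set_press_inflows(cfg, sched$press_inflow_factor) else cfg
    event_end <- sched$pre_updates + sched$press_duration
    state <- step_update(state, event_cfg, sched$press_duration,
                         capture_at = event_end)
    pops[["post"]] <- attr(state, "captures")[[1]]
    snap_update["post"] <- event_end
  }

  # recovery under restored inflows
  offsets <- setdiff(sched$sampling_offsets, 0L)
  if (sched$recovery_updates > 0) {
    caps <- event_end + offsets
    state <- step_update(state, cfg, sched$recovery_updates, capture_at = caps)
    got <- attr(state, "captures")
    for (i in seq_along(offsets)) {
      lab <- paste0("rec", offsets[i])
      pops[[lab]] <- got[[i]]
      snap_update[lab] <- caps[i]
    }
  }

  res <- list(
    log = genealogy_log(state),
    snapshots = data.frame(label = names(snap_update),
                           update = unname(snap_update),
                           stringsAsFactors = FALSE),
    populations = pops,
    config = cfg,
    schedule = sched,
    seed = as.integer(seed),
    failed = state$failed
  )
  class(res) <- "eco_experiment"
  res
}

#' @export
print.eco_experiment <- function(x, ...) {
  cat("<eco_experiment>", treatment_label(x$schedule),
      "| seed", x$seed,
      "|", nrow(x$log), "genotypes |",
      nrow(x$snapshots), "snapshots",
      if (x$failed) "| FAILED" else "", "\n")
  invisible(x)
}

#' Genealogy log of a state or experiment
#'
#' Per-genotype records from which all phylogenies derive.  A genotype is
#' extant at time `t` iff `origin_update <= t` and `extinction_update` is
#' `NA` or `> t` (extinction is stamped with the update during which the last
#' organism disappeared).
#'
#' @param x An `eco_state` or `eco_experiment`.
#' @return A data frame with columns `genotype_id`, `parent_id` (`NA` for the
#'   founder), `origin_update`, `extinction_update` (`NA` while extant),
#'   `n_traits`, `viable`, `traits`, `tag`.
#' @export
genealogy_log <- function(x) {
  if (inherits(x, "eco_experiment")) return(x$log)
  stopifnot(inherits(x, "eco_state"))
  g <- x$genealogy
  data.frame(
    genotype_id = seq_along(g$parent),
    parent_id = ifelse(g$parent == 0L, NA_integer_, g$parent),
    origin_update = g$origin,
    extinction_update = ifelse(g$extinct == -1L, NA_integer_, g$extinct),
    n_traits = g$ntraits,
    viable = g$viable == 1L,
    traits = g$traits,
    tag = g$tag,
    stringsAsFactors = FALSE
  )
}

#' Genotypes extant at a time point
#'
#' @param log A genealogy log data frame.
#' @param t Time in updates.
#' @return Integer vector of genotype ids extant at `t`.
#' @export
extant_genotypes <- function(log, t) {
  log$genotype_id[log$origin_update <= t &
                    (is.na(log$extinction_update) | log$extinction_update > t)]
}

#' Mean trait count of a population snapshot
#'
#' @param experiment An `eco_experiment`.
#' @param label Snapshot label (e.g. "pre", "post").
#' @return Mean number of traits per organism in that snapshot.
#' @export
snapshot_mean_traits <- function(experiment, label) {
  org <- experiment$populations[[label]]
  if (is.null(org)) stop("no snapshot labelled '", label, "'")
  mean(experiment$log$n_traits[org])
}

#' Write / read a genealogy log as TSV
#'
#' Columns: `genotype_id`, `parent_id`, `origin_update`, `extinction_update`
#' (empty while extant at end of run), `n_traits`, `viable`.  Ids are written
#' as opaque strings.
#'
#' @param log A genealogy log data frame.
#' @param path File path.
#' @return `read_genealogy_tsv` returns the log data frame.
#' @export
write_genealogy_tsv <- function(log, path) {
  out <- log[, c("genotype_id", "parent_id", "origin_update",
                 "extinction_update", "n_traits", "viable")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_genealogy_tsv
#' @export
read_genealogy_tsv <- function(path) {
  log <- utils::read.table(path, sep = "\t", header = TRUE,
                           na.strings = "", stringsAsFactors = FALSE)
  needed <- c("genotype_id", "parent_id", "origin_update",
              "extinction_update", "n_traits", "viable")
  missing <- setdiff(needed, names(log))
  if (length(missing))
    stop("genealogy TSV lacks columns: ", paste(missing, collapse = ", "))
  log$viable <- as.logical(log$viable)
  log
}
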