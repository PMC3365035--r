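#' Resource cascade topology
#'
#' The community competes for one depletable resource per logic function.
#' Only the two basal resources (NOT, NAND) flow in exogenously; every other
#' resource exists solely as a by-product of consumption one level up the
#' cascade: an organism performing a function consumes its resource and, per
#' `conversion_factor` units consumed, releases one unit of each downstream
#' resource.  Edges: NOT and NAND each feed \{AND, ORN, OR\}; AND feeds
#' \{ANDN, NOR, XOR\}; ANDN feeds \{EQU\}.
#'
#' @return A list with `functions` (names), `levels` (cascade depth, 1 =
#'   basal), and `downstream` (list of integer vectors of fed functions).
#' @export
resource_cascade <- function() {
  fun <- c("NOT", "NAND", "AND", "ORN", "OR", "ANDN", "NOR", "XOR", "EQU")
  levels <- c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L)
  downstream <- list(
    NOT  = c(3L, 4L, 5L),
    NAND = c(3L, 4L, 5L),
    AND  = c(6L, 7L, 8L),
    ORN  = integer(0),
    OR   = integer(0),
    ANDN = c(9L),
    NOR  = integer(0),
    XOR  = integer(0),
    EQU  = integer(0)
  )
  list(functions = fun, levels = levels, downstream = downstream)
}

#' Ecology configuration
#'
#' Parameters of the digital ecology: a fixed-capacity, well-mixed population
#' of asexual replicators whose genotypes are (trait bit-vector, neutral tag)
#' pairs.  Merit rewards double with cascade depth, so deep functions pay more
#' but depend on the whole chain of by-products below them.
#'
#' @param population_size Community capacity in organisms (default 3600).
#' @param n_functions Number of resource-linked functions (default 9).
#' @param rewards Per-function merit reward; default doubles per cascade
#'   level, `2^(level - 1)`.
#' @param inflow Per-resource exogenous inflow (resource units/update);
#'   nonzero only for the two basal resources by default.
#' @param decay Fractional resource outflow per update, in (0, 1).
#' @param uptake_fraction Fraction of a resource pool removed per update when
#'   at least one organism performs the function, shared equally among
#'   performers; in (0, 1].
#' @param conversion_factor Units of consumed resource needed per unit of each
#'   downstream by-product (default 3).
#' @param base_merit Merit available to every viable organism regardless of
#'   traits; keeps trait-free replicators viable.
#' @param trait_cost Per-function increment to gestation effort; fitness is
#'   divided by `1 + trait_cost * n_traits`.
#' @param birth_rate Expected births per organism per update.
#' @param mu_trait Per-function gain/loss mutation probability per birth.
#' @param mu_tag Neutral-tag mutation probability per birth; this is the main
#'   engine of near-neutral cladogenesis.
#' @param mu_lethal Probability a birth is non-viable.
#' @return An object of class `ecology_config`.
#' @export
ecology_config <- function(population_size = 3600L,
                           n_functions = 9L,
                           rewards = NULL,
                           inflow = NULL,
                           decay = 0.01,
                           uptake_fraction = 0.25,
                           conversion_factor = 3,
                           base_merit = 1,
                           trait_cost = 0.5,
                           birth_rate = 0.2,
                           mu_trait = 0.0003,
                           mu_tag = 0.05,
                           mu_lethal = 0.01) {
  cascade <- resource_cascade()
  if (n_functions != length(cascade$functions))
    stop("n_functions must match the cascade topology (", length(cascade$functions), ")")
  if (is.null(rewards)) rewards <- 2^(cascade$levels - 1)
  if (is.null(inflow)) {
    inflow <- numeric(n_functions)
    inflow[cascade$levels == 1L] <- 100
  }
  cfg <- list(
    population_size = as.integer(population_size),
    n_functions = as.integer(n_functions),
    rewards = as.numeric(rewards),
    inflow = as.numeric(inflow),
    decay = decay,
    uptake_fraction = uptake_fraction,
    conversion_factor = conversion_factor,
    base_merit = base_merit,
    trait_cost = trait_cost,
    birth_rate = birth_rate,
    mu_trait = mu_trait,
    mu_tag = mu_tag,
    mu_lethal = mu_lethal,
    downstream = unname(cascade$downstream),
    function_names = cascade$functions
  )
  class(cfg) <- "ecology_config"
  validate_ecology_config(cfg)
  cfg
}

validate_ecology_config <- function(cfg) {
  stopifnot(
    cfg$population_size >= 2L,
    length(cfg$rewards) == cfg$n_functions,
    all(cfg$rewards > 0),
    length(cfg$inflow) == cfg$n_functions,
    all(cfg$inflow >= 0),
    cfg$decay > 0, cfg$decay < 1,
    cfg$uptake_fraction > 0, cfg$uptake_fraction <= 1,
    cfg$conversion_factor > 0,
    cfg$base_merit > 0,
    cfg$trait_cost >= 0,
    cfg$birth_rate > 0
  )
  for (p in c("mu_trait", "mu_tag", "mu_lethal"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  invisible(cfg)
}

#' @export
print.ecology_config <- function(x, ...) {
  cat("<ecology_config> N =", x$population_size,
      "| functions =", x$n_functions,
      "| basal inflow =", paste(x$inflow[x$inflow > 0], collapse = "/"),
      "| mu (trait/tag/lethal) =",
      paste(x$mu_trait, x$mu_tag, x$mu_lethal, sep = "/"), "\n")
  invisible(x)
}

#' Reduce exogenous inflows for a press episode
#'
#' Returns a configuration whose every exogenous inflow is multiplied by
#' `factor` (0.01 for a strong press, 0.1 for a weak press); all other fields
#' are untouched.  The organism-free equilibrium of each basal resource,
#' `inflow / decay`, scales by exactly `factor`.
#'
#' @param cfg An `ecology_config`.
#' @param factor Multiplier in (0, 1].
#' @return The modified `ecology_config`.
#' @export
set_press_inflows <- function(cfg, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 || factor > 1)
    stop("press inflow factor must be a single value in (0, 1]")
  cfg$inflow <- cfg$inflow * factor
  cfg
}

#' Treatment schedule
#'
#' Declarative description of one experimental treatment: unperturbed control,
#' instantaneous pulse cull, or press episode of reduced basal inflows.  The
#' control carries an event window of the press duration with factor 1 so that
#' all treatments share absolute timing (a 205,000-update control aligns with
#' 100,000 + 5,000 + 100,000 press runs at paper scale).
#'
#' @param kind One of "control", "pulse", "press".
#' @param strength "strong", "weak", or "none" (control).
#' @param pre_updates Updates of unperturbed evolution before the event.
#' @param press_duration Event-window length in updates (also the control's
#'   alignment window).
#' @param press_inflow_factor Inflow multiplier during a press (strong 0.01,
#'   weak 0.1).
#' @param pulse_survivors Organisms kept by a pulse cull (strong 4, weak 36).
#' @param recovery_updates Updates after the event.
#' @param sampling_offsets Updates into the recovery at which snapshots are
#'   taken; 0 is the immediate post-event point, and the immediate pre-event
#'   snapshot is always captured.
#' @return An object of class `treatment_schedule`.
#' @export
treatment_schedule <- function(kind = c("control", "pulse", "press"),
                               strength = c("none", "strong", "weak"),
                               pre_updates = 100000L,
                               press_duration = 5000L,
                               press_inflow_factor = NULL,
                               pulse_survivors = NULL,
                               recovery_updates = 100000L,
                               sampling_offsets = c(0L, 2000L, 5000L, 10000L,
                                                    25000L, 50000L, 75000L,
                                                    100000L)) {
  kind <- match.arg(kind)
  strength <- match.arg(strength)
  if (kind == "control") strength <- "none"
  if (kind != "control" && strength == "none")
    stop("pulse/press treatments need strength 'strong' or 'weak'")
  if (kind == "press" && is.null(press_inflow_factor))
    press_inflow_factor <- switch(strength, strong = 0.01, weak = 0.1)
  if (kind == "pulse" && is.null(pulse_survivors))
    pulse_survivors <- switch(strength, strong = 4L, weak = 36L)
  sampling_offsets <- sort(unique(as.integer(sampling_offsets)))
  sched <- list(
    kind = kind,
    strength = strength,
    pre_updates = as.integer(pre_updates),
    press_duration = as.integer(press_duration),
    press_inflow_factor = press_inflow_factor,
    pulse_survivors = if (!is.null(pulse_survivors)) as.integer(pulse_survivors),
    recovery_updates = as.integer(recovery_updates),
    sampling_offsets = sampling_offsets
  )
  class(sched) <- "treatment_schedule"
  validate_treatment_schedule(sched)
  sched
}

validate_treatment_schedule <- function(sched) {
  stopifnot(
    sched$pre_updates > 0,
    sched$recovery_updates >= 0,
    all(sched$sampling_offsets >= 0),
    all(sched$sampling_offsets <= sched$recovery_updates),
    !is.unsorted(sched$sampling_offsets)
  )
  if (sched$kind == "press") {
    stopifnot(sched$press_duration > 0)
    f <- sched$press_inflow_factor
    if (f <= 0 || f > 1) stop("press_inflow_factor must lie in (0, 1]")
  }
  if (sched$kind == "pulse") {
    if (is.null(sched$pulse_survivors) || sched$pulse_survivors < 2L)
      stop("pulse_survivors must be at least 2")
  }
  invisible(sched)
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat("<treatment_schedule>", x$kind, x$strength,
      "| pre =", x$pre_updates,
      "| event =", if (x$kind == "pulse") "instantaneous" else x$press_duration,
      "| recovery =", x$recovery_updates, "\n")
  invisible(x)
}

#' Named treatment label
#' @param sched A `treatment_schedule`.
#' @return A short label such as "control" or "press-strong".
#' @export
treatment_label <- function(sched) {
  if (sched$kind == "control") "control" else paste(sched$kind, sched$strength, sep = "-")
}

#' Study profiles
#'
#' `paper_profile()` returns the full-scale study conditions (3600 organisms,
#' 100,000 + 5,000 + 100,000 updates, culls to 4 / 36 survivors).
#' `desk_profile()` is a reduced profile for routine analysis and testing:
#' 400 organisms, 10,000 + 1,000 + 10,000 updates, the same cull sizes and
#' press factors, and proportionally spaced sampling offsets.
#'
#' @param treatment One of "control", "pulse-strong", "pulse-weak",
#'   "press-strong", "press-weak".
#' @return A list with elements `config` and `schedule`.
#' @export
desk_profile <- function(treatment = c("control", "pulse-strong", "pulse-weak",
                                       "press-strong", "press-weak")) {
  treatment <- match.arg(treatment)
  cfg <- ecology_config(population_size = 400L)
  sched <- make_schedule(treatment,
                         pre_updates = 10000L,
                         press_duration = 1000L,
                         recovery_updates = 10000L,
                         sampling_offsets = c(0L, 500L, 1000L, 2500L, 5000L,
                                              7500L, 10000L))
  list(config = cfg, schedule = sched)
}

#' @rdname desk_profile
#' @export
paper_profile <- function(treatment = c("control", "pulse-strong", "pulse-weak",
                                        "press-strong", "press-weak")) {
  treatment <- match.arg(treatment)
  cfg <- ecology_config(population_size = 3600L)
  sched <- make_schedule(treatment,
                         pre_updates = 100000L,
                         press_duration = 5000L,
                         recovery_updates = 100000L,
                         sampling_offsets = c(0L, 2000L, 5000L, 10000L, 25000L,
                                              50000L, 75000L, 100000L))
  list(config = cfg, schedule = sched)
}

make_schedule <- function(treatment, ...) {
  parts <- strsplit(treatment, "-", fixed = TRUE)[[1]]
  kind <- parts[1]
  strength <- if (length(parts) > 1) parts[2] else "none"
  treatment_schedule(kind = kind, strength = strength, ...)
}
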