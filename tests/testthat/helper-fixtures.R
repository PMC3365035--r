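# Fixture builders: hand-written genealogy logs and random log generation.

# The worked four-genotype genealogy: founder G1 (extinct), G2 and G4 children
# of G1 at updates 10 and 20, G3 child of G2 at 30; extant at 100: G2, G4, G3.
# Pruning collapses the update-20 event (single surviving line) and yields
# ((G2, G3) at 30, G4-as-…) — root at age 10.
worked_log <- function() {
  data.frame(
    genotype_id = c("G1", "G2", "G4", "G3"),
    parent_id = c(NA, "G1", "G1", "G2"),
    origin_update = c(0L, 10L, 20L, 30L),
    extinction_update = c(50L, NA, NA, NA),
    n_traits = 0L, viable = TRUE,
    stringsAsFactors = FALSE
  )
}

# Random valid genealogy log: origins strictly increase along parent chains;
# extinctions strike a fraction of genotypes at a random later update.
random_log <- function(n_genotypes, p_extinct = 0.35, max_gap = 20L) {
  parent <- c(NA_integer_, vapply(2:n_genotypes, function(i)
    sample.int(i - 1L, 1L), 1L))
  origin <- integer(n_genotypes)
  for (i in 2:n_genotypes)
    origin[i] <- origin[parent[i]] + sample.int(max_gap, 1L)
  ext <- ifelse(stats::runif(n_genotypes) < p_extinct,
                origin + sample.int(60L, n_genotypes, replace = TRUE),
                NA_integer_)
  # a parent must outlive (or at least reach) every child's origin
  for (i in 2:n_genotypes) {
    j <- parent[i]
    if (!is.na(ext[j]) && ext[j] < origin[i]) ext[j] <- origin[i]
  }
  data.frame(
    genotype_id = as.character(seq_len(n_genotypes)),
    parent_id = as.character(parent),
    origin_update = origin,
    extinction_update = as.integer(ext),
    n_traits = 0L, viable = TRUE,
    stringsAsFactors = FALSE
  )
}

# Random log guaranteed to have >= 2 extant genotypes at the returned sample
# time (resampled until it does).
random_log_with_tips <- function(n_genotypes, ...) {
  repeat {
    log <- random_log(n_genotypes, ...)
    sample_time <- max(log$origin_update) + sample.int(20L, 1L)
    if (length(extant_genotypes(log, sample_time)) >= 2L)
      return(list(log = log, sample_time = sample_time))
  }
}

# Minimal hand-built eco_state with an explicit genotype table, for stepping
# the resource/consumption dynamics under controlled conditions.
manual_state <- function(cfg, traits, counts, viable = NULL, resources = NULL) {
  if (is.null(viable)) viable <- rep(1L, length(traits))
  if (is.null(resources)) resources <- cfg$inflow / cfg$decay
  organisms <- rep(seq_along(traits), counts)
  state <- list(
    organisms = as.integer(organisms),
    resources = as.numeric(resources),
    update = 0L,
    next_tag = 1L,
    genealogy = list(
      parent = c(0L, rep(1L, length(traits) - 1L)),
      origin = c(0L, rep(0L, length(traits) - 1L)),
      extinct = rep(-1L, length(traits)),
      traits = as.integer(traits),
      tag = seq_along(traits) - 1L,
      viable = as.integer(viable),
      count = as.integer(counts),
      ntraits = vapply(traits, function(x) sum(bitwAnd(x, 2^(0:8)) > 0), 0)
    ),
    failed = FALSE
  )
  class(state) <- "eco_state"
  state
}

# Tiny press schedule used for selectivity properties (5,000 + 500 updates).
mini_press_schedule <- function(factor = 0.01) {
  treatment_schedule(kind = "press", strength = "strong",
                     pre_updates = 5000L, press_duration = 500L,
                     press_inflow_factor = factor,
                     recovery_updates = 0L, sampling_offsets = 0L)
}
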