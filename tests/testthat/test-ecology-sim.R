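test_that("resources relax to the inflow/decay fixed point without consumers", {
  cfg <- ecology_config(population_size = 10L, mu_trait = 0, mu_tag = 0,
                        mu_lethal = 0)
  # founder bears no traits, so nothing is consumed; start far from equilibrium
  state <- init_ecology_state(cfg, resources = rep(0, cfg$n_functions))
  set.seed(1)
  state <- step_update(state, cfg, n_updates = 5000L)
  expect_equal(state$resources, cfg$inflow / cfg$decay, tolerance = 1e-6)
})

test_that("with all mutation rates zero the genealogy is forever the founder alone", {
  cfg <- ecology_config(population_size = 50L, mu_trait = 0, mu_tag = 0,
                        mu_lethal = 0)
  state <- init_ecology_state(cfg)
  set.seed(2)
  state <- step_update(state, cfg, n_updates = 500L)
  log <- genealogy_log(state)
  expect_equal(nrow(log), 1L)
  expect_true(is.na(log$parent_id))
  expect_true(is.na(log$extinction_update))
  expect_equal(length(state$organisms), 50L)
})

test_that("two hand-iterated updates of uptake and by-product conversion match", {
  cfg <- ecology_config(population_size = 5L, mu_trait = 0, mu_tag = 0,
                        mu_lethal = 0, birth_rate = 1e-8)
  # one NOT-performer (trait bit 1) among trait-free organisms
  state <- manual_state(cfg, traits = c(0L, 1L), counts = c(4L, 1L))
  C0 <- cfg$inflow / cfg$decay
  set.seed(3)
  state <- step_update(state, cfg, n_updates = 2L)

  # oracle: hand-iterate decay -> inflow -> single-performer uptake -> by-products
  C <- C0
  for (i in 1:2) {
    C <- (1 - cfg$decay) * C + cfg$inflow
    consumed <- cfg$uptake_fraction * C[1]
    C[1] <- C[1] - consumed
    C[3:5] <- C[3:5] + consumed / cfg$conversion_factor  # NOT feeds AND/ORN/OR
  }
  expect_equal(state$resources, C, tolerance = 1e-10)
})

test_that("population size is restored to capacity at update boundaries", {
  prof <- desk_profile("pulse-strong")
  cfg <- ecology_config(population_size = 100L)
  sched <- treatment_schedule("pulse", "strong", pre_updates = 300L,
                              recovery_updates = 500L,
                              sampling_offsets = c(0L, 500L))
  exp <- run_experiment(cfg, sched, seed = 11)
  expect_equal(length(exp$populations[["pre"]]), 100L)
  expect_equal(length(exp$populations[["post"]]), 4L)   # just culled
  expect_equal(length(exp$populations[["rec500"]]), 100L)  # refilled
})

test_that("identical config, schedule and seed reproduce the run exactly", {
  prof <- desk_profile("press-strong")
  cfg <- ecology_config(population_size = 100L)
  sched <- treatment_schedule("press", "strong", pre_updates = 400L,
                              press_duration = 100L, recovery_updates = 200L,
                              sampling_offsets = c(0L, 200L))
  a <- run_experiment(cfg, sched, seed = 99)
  b <- run_experiment(cfg, sched, seed = 99)
  expect_identical(a$log, b$log)
  expect_identical(a$populations, b$populations)
  c <- run_experiment(cfg, sched, seed = 100)
  expect_false(identical(a$log, c$log))
})

test_that("pulse cull keeps exactly k viable organisms and only viable ones", {
  cfg <- ecology_config(population_size = 200L)
  state <- manual_state(cfg, traits = c(0L, 0L), counts = c(150L, 50L),
                        viable = c(1L, 0L))
  set.seed(4)
  culled <- apply_pulse_cull(state, 10L)
  expect_equal(length(culled$organisms), 10L)
  expect_true(all(culled$genealogy$viable[culled$organisms] == 1L))

  # identity cull: keeping everyone leaves the multiset unchanged
  all_viable <- manual_state(cfg, traits = 0L, counts = 200L)
  same <- apply_pulse_cull(all_viable, 200L)
  expect_equal(sort(same$organisms), sort(all_viable$organisms))

  # too few viable organisms is an explicit failure
  expect_error(apply_pulse_cull(state, 151L), "viable")
})

test_that("press inflow scaling is exact and reversible", {
  cfg <- ecology_config()
  strong <- set_press_inflows(cfg, 0.01)
  expect_equal(strong$inflow, cfg$inflow * 0.01)
  expect_equal(strong$inflow / strong$decay,
               0.01 * cfg$inflow / cfg$decay)     # equilibrium drops 100-fold
  weak <- set_press_inflows(cfg, 0.1)
  expect_equal(weak$inflow[weak$inflow > 0] / cfg$inflow[cfg$inflow > 0],
               rep(0.1, 2))
  expect_equal(set_press_inflows(cfg, 1), cfg)
  expect_error(set_press_inflows(cfg, 0), "factor")
  expect_error(set_press_inflows(cfg, -0.5), "factor")
})

test_that("a strong press selects against trait-bearing organisms", {
  # disaster-taxa selectivity: across seeded replicates the mean trait count
  # per organism drops over the press window (one-sided sign test)
  cfg <- ecology_config(population_size = 400L)
  sched <- mini_press_schedule(0.01)
  drops <- vapply(1:20, function(s) {
    exp <- run_experiment(cfg, sched, seed = 7000 + s)
    snapshot_mean_traits(exp, "post") < snapshot_mean_traits(exp, "pre")
  }, TRUE)
  p <- stats::binom.test(sum(drops), length(drops), p = 0.5,
                         alternative = "greater")$p.value
  expect_lt(p, 0.05)
})

test_that("genealogy logs round-trip through TSV", {
  cfg <- ecology_config(population_size = 60L)
  sched <- treatment_schedule("control", pre_updates = 300L,
                              press_duration = 50L, recovery_updates = 100L,
                              sampling_offsets = c(0L, 100L))
  exp <- run_experiment(cfg, sched, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genealogy_tsv(exp$log, path)
  back <- read_genealogy_tsv(path)
  expect_equal(back$origin_update, exp$log$origin_update)
  expect_equal(back$extinction_update, exp$log$extinction_update)
  expect_equal(as.character(back$parent_id),
               as.character(exp$log$parent_id))
})

test_that("genealogy origins are strictly ordered along parent chains", {
  cfg <- ecology_config(population_size = 80L)
  sched <- treatment_schedule("control", pre_updates = 500L,
                              press_duration = 50L, recovery_updates = 0L,
                              sampling_offsets = 0L)
  exp <- run_experiment(cfg, sched, seed = 21)
  log <- exp$log
  pid <- match(log$parent_id, log$genotype_id)
  ok <- !is.na(pid)
  expect_true(all(log$origin_update[ok] > log$origin_update[pid[ok]]))
  expect_true(all(is.na(log$extinction_update) |
                    log$extinction_update >= log$origin_update))
})
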