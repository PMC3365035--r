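test_that("node ages bin into half-open intervals anchored at zero", {
  b <- bin_node_ages(c(10, 4999, 5000), 5000)
  expect_equal(unname(b$counts), c(2L, 1L))   # 5000 goes to the upper bin
  expect_equal(names(b$counts), c("0", "1"))
  expect_equal(sum(bin_node_ages(numeric(0), 5000)$counts), 0L)
  # hand tally with a coarser width
  ages <- c(500, 9000, 9999, 10000, 15000, 29999)
  expect_equal(unname(bin_node_ages(ages, 10000)$counts), c(3L, 2L, 1L))
})

test_that("percent retention applies the exclusion and zero rules", {
  pre <- bin_node_ages(c(rep(100, 3), rep(5100, 2), rep(15100, 5)), 5000)
  post <- bin_node_ages(c(rep(100, 2), rep(15100, 5)), 5000)
  r <- percent_retention(pre, post)
  expect_equal(r$retention, c(100 * 2 / 3, 0, NA, 100))
  expect_equal(r$excluded, c(FALSE, FALSE, TRUE, FALSE))

  # identity: 100 in every nonempty bin
  same <- percent_retention(pre, pre)
  expect_true(all(same$retention[!same$excluded] == 100))

  # a bin gaining nodes violates the subset invariant
  expect_error(percent_retention(bin_node_ages(c(100), 5000),
                                 bin_node_ages(c(100, 5100), 5000)),
               "subset")
  expect_error(percent_retention(bin_node_ages(1, 5000),
                                 bin_node_ages(1, 1000)),
               "bin width")
})

test_that("aggregation includes zeros and reports two standard errors", {
  pre <- bin_node_ages(c(100, 100), 5000)
  t1 <- percent_retention(pre, bin_node_ages(c(100, 100), 5000)) # 100
  t2 <- percent_retention(pre, bin_node_ages(numeric(0), 5000))  # 0
  agg <- aggregate_retention(list(t1, t2))
  expect_equal(agg$mean, 50)
  expect_equal(agg$two_se, 100)    # sd(c(100,0))/sqrt(2) * 2
  expect_equal(agg$n_replicates, 2L)

  # replicates with an empty reference bin don't contribute there
  deep_pre <- bin_node_ages(c(100, 6000), 5000)
  t3 <- percent_retention(deep_pre, bin_node_ages(c(100, 6000), 5000))
  agg2 <- aggregate_retention(list(t1, t3))
  expect_equal(agg2$n_replicates, c(2L, 1L))

  all100 <- aggregate_retention(list(t1, t1, t1))
  expect_equal(all100$mean, 100)
})

test_that("retention is bounded and non-increasing through the recovery", {
  cfg <- ecology_config(population_size = 150L)
  sched <- treatment_schedule("control", pre_updates = 2000L,
                              press_duration = 200L,
                              recovery_updates = 2000L,
                              sampling_offsets = c(0L, 1000L, 2000L))
  for (s in 1:5) {
    exp <- run_experiment(cfg, sched, seed = 900 + s)
    pre_tree <- tryCatch(
      build_tree(exp$log, 2000, extant = unique(exp$populations[["pre"]])),
      error = function(e) NULL)
    if (is.null(pre_tree)) next
    pre_b <- bin_node_ages(ltt(pre_tree)$branching_ages, 500)
    prev_mean <- Inf
    for (lab in c("post", "rec1000", "rec2000")) {
      up <- exp$snapshots$update[exp$snapshots$label == lab]
      tree <- tryCatch(
        build_tree(exp$log, up, extant = unique(exp$populations[[lab]])),
        error = function(e) NULL)
      ages <- if (is.null(tree)) numeric(0) else
        prune_nodes_after(ltt(tree)$branching_ages, 2000)
      r <- percent_retention(pre_b, bin_node_ages(ages, 500))
      vals <- r$retention[!is.na(r$retention)]
      expect_true(all(vals >= 0 & vals <= 100))
      m <- mean(vals)
      expect_lte(m, prev_mean + 1e-9)
      prev_mean <- m
    }
  }
})

test_that("root retention tracks the identity of the basal branching event", {
  log <- worked_log()
  pre <- build_tree(log, 100)
  expect_true(root_retained(pre, pre))

  # G4's line dies in the recovery: the root moves to the update-30 event
  log2 <- log
  log2$extinction_update[log2$genotype_id == "G4"] <- 150L
  post <- build_tree(log2, 200)
  expect_equal(post$root_age, 30)
  expect_false(root_retained(pre, post))
  expect_gt(post$root_age, pre$root_age)

  # same root age but a different host genotype is not the same event
  fake <- pre
  fake$root_host <- "G9"
  expect_false(root_retained(pre, fake))
})

test_that("root-age histograms report event-relative fractions", {
  d <- data.frame(timepoint = "end", root_age = c(854, 6000, 101000))
  h <- root_age_histogram(d, bin_width = 5000,
                          event_window = c(100000, 105000))
  expect_equal(sum(h$counts$count), 3L)
  expect_equal(h$fractions$frac_young, 1 / 3)
  expect_equal(h$fractions$frac_during_event, 1 / 3)
  expect_equal(h$fractions$frac_after_event, 0)

  all_young <- root_age_histogram(
    data.frame(timepoint = "pre", root_age = c(10, 200, 4999)), 5000)
  expect_equal(nrow(all_young$counts), 1L)
  expect_equal(all_young$fractions$frac_young, 1)

  empty <- root_age_histogram(data.frame(timepoint = character(0),
                                         root_age = numeric(0)), 5000)
  expect_equal(nrow(empty$counts), 0L)
})

test_that("turnover counts partition originations, extinctions, persistences", {
  # zero-mutation log: just the founder persisting
  founder <- data.frame(genotype_id = "F", parent_id = NA,
                        origin_update = 0L, extinction_update = NA_integer_,
                        n_traits = 0L, viable = TRUE)
  expect_equal(unname(turnover_counts(founder, c(10, 20))), c(0L, 0L, 1L))

  log <- data.frame(
    genotype_id = c("A", "B", "C", "D"),
    parent_id = c(NA, "A", "A", "B"),
    origin_update = c(0L, 5L, 12L, 18L),
    extinction_update = c(15L, NA, 25L, NA),
    n_traits = 0L, viable = TRUE
  )
  tc <- turnover_counts(log, c(10, 20))
  expect_equal(unname(tc), c(2L, 1L, 1L))  # C,D originate; A dies; B persists

  expect_equal(unname(turnover_counts(log, c(-10, 0))), c(0L, 0L, 0L))
  expect_error(turnover_counts(log, c(20, 10)), "t0 < t1")
})
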