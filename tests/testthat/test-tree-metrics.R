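test_that("ltt extracts branching ages and internode intervals", {
  tree <- from_newick("(G2:90,(G1:70,G3:70):20):10;")
  s <- ltt(tree)
  expect_equal(s$branching_ages, c(10, 30))
  expect_equal(s$n, 3L)
  expect_equal(s$g, c(20, 70))   # g_2, g_3

  # multifurcating root: simultaneous splits, zero-length g_2
  tri <- from_newick("(A:5,B:5,C:5):5;")
  s2 <- ltt(tri)
  expect_equal(s2$branching_ages, c(5, 5))
  expect_equal(s2$g, c(0, 5))

  two <- from_newick("(A:7,B:7):3;")
  expect_equal(ltt(two)$g, 7)    # g_2 = sample - root age
})

test_that("gamma reproduces hand-computed worked values", {
  # symmetric 3-tip case: A_2 = T/2 exactly
  expect_equal(pybus_harvey_gamma(make_ltt(c(0, 3), 5)), 0)
  # equal internode intervals, n = 4: T = 9, mean A = 3.5
  g4 <- make_ltt(c(0, 1, 2), 3)
  expect_equal(pybus_harvey_gamma(g4), -1 / (9 * sqrt(1 / 24)),
               tolerance = 1e-12)
  expect_equal(pybus_harvey_gamma(g4), -0.5443, tolerance = 1e-4)
  # the worked 3-tip tree: A_2 = 40, T = 250
  tree <- from_newick("(G2:90,(G1:70,G3:70):20):10;")
  expect_equal(pybus_harvey_gamma(tree), (40 - 125) / (250 * sqrt(1 / 12)),
               tolerance = 1e-12)
  expect_equal(pybus_harvey_gamma(tree), -1.1778, tolerance = 1e-4)
})

test_that("gamma is undefined below three tips and invariant to time rescaling", {
  expect_error(pybus_harvey_gamma(make_ltt(5, 10)), "fewer than 3")
  set.seed(31)
  for (i in 1:10) {
    s <- yule_ltt(20)
    scaled <- make_ltt(s$branching_ages * 7, s$sample_time * 7)
    expect_equal(pybus_harvey_gamma(scaled), pybus_harvey_gamma(s),
                 tolerance = 1e-9)
  }
})

test_that("gamma agrees with the unit-step sweep oracle on random trees", {
  set.seed(12)
  checked <- 0L
  while (checked < 50L) {
    fix <- random_log_with_tips(12L)
    tree <- build_tree(fix$log, fix$sample_time)
    if (tree$n_tips < 3L) next
    checked <- checked + 1L
    s <- ltt(tree)
    expect_equal(pybus_harvey_gamma(s),
                 gamma_unit_sweep(s$branching_ages, s$sample_time),
                 tolerance = 1e-9)
  }
})

test_that("gamma agrees with ape's implementation on bifurcating trees", {
  set.seed(13)
  for (i in 1:20) {
    s <- yule_ltt(25)
    phy <- ape::rcoal(25)   # any ultrametric bifurcating tree will do
    tree <- from_newick(ape::write.tree(phy))
    expect_equal(pybus_harvey_gamma(tree), ape::gammaStat(phy),
                 tolerance = 1e-6)
  }
})

test_that("moving branching events tipward increases gamma", {
  # hold n and total depth fixed; slide interior events later
  base <- c(0, 10, 20, 30, 40)          # 6 tips, sample at 100
  for (shift in c(5, 20, 40)) {
    shifted <- c(0, base[-1] + shift)
    expect_gt(pybus_harvey_gamma(make_ltt(shifted, 100)),
              pybus_harvey_gamma(make_ltt(base, 100)))
    # the sweep oracle agrees on the ordering
    expect_gt(gamma_unit_sweep(shifted, 100), gamma_unit_sweep(base, 100))
  }
})

test_that("yule trees calibrate gamma to the standard normal", {
  set.seed(500)
  n_rep <- 500L
  gs <- vapply(seq_len(n_rep), function(i) pybus_harvey_gamma(yule_ltt(50)),
               0)
  expect_lt(abs(mean(gs)), 3 * stats::sd(gs) / sqrt(n_rep))
  expect_gt(stats::var(gs), 0.8)
  expect_lt(stats::var(gs), 1.25)
})

test_that("stemminess reproduces the worked values in both variants", {
  # balanced four-tip tree: stems 2 and 2, all tip branches 1
  bal <- from_newick("((A:1,B:1):2,(C:1,D:1):2):0;")
  expect_equal(ncs(bal, "rohlf1990")$value, 0.5)
  expect_equal(ncs(bal, "inverse-ratio")$value, 1.0)

  tree <- from_newick("(G2:90,(G1:70,G3:70):20):10;")
  expect_equal(ncs(tree, "rohlf1990")$value, 20 / 160)

  # lengthening the basal stem (node age 30 -> 90) raises stemminess
  long <- from_newick("(G2:90,(G1:10,G3:10):80):10;")
  expect_equal(ncs(long, "rohlf1990")$value, 80 / 100)
})

test_that("rohlf stemminess is bounded and increases with basal stem length", {
  set.seed(77)
  for (i in 1:20) {
    fix <- random_log_with_tips(15L)
    tree <- build_tree(fix$log, fix$sample_time)
    v <- tryCatch(ncs(tree, "rohlf1990")$value, error = function(e) NA)
    if (!is.na(v)) { expect_gte(v, 0); expect_lte(v, 1) }
  }
  # single internal node: stem l at the expense of its children's branches
  vals <- vapply(c(10, 40, 60, 80), function(l) {
    nwk <- sprintf("(G2:90,(G1:%g,G3:%g):%g):10;", 90 - l, 90 - l, l)
    ncs(from_newick(nwk), "rohlf1990")$value
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("zero-length stems are skipped with a count, not treated as infinite", {
  # inner node at the same age as the root (zero stem)
  tree <- from_newick("((A:5,B:5):0,(C:4,D:4):1):2;")
  r <- ncs(tree, "inverse-ratio")
  expect_equal(r$n_skipped, 1L)
  expect_equal(r$n_internal_nodes, 1L)
  expect_equal(r$value, (4 + 4) / 1)
  expect_error(ncs(from_newick("(A:3,B:3):1;")), "no internal non-root")
})

test_that("root age and root-gap distances follow the branching-age conventions", {
  tree <- from_newick("(G2:90,(G1:70,G3:70):20):10;")
  expect_equal(root_age(tree), 10)
  gaps <- root_gap_distances(tree)
  expect_equal(unname(gaps["d1"]), 20)
  expect_true(is.na(gaps["d2"]))     # only two branching events

  ext <- from_newick("((G1:70,G4:70):20,(G2:70,G3:70):20,G5:90):10;")
  # events at 10 (x2, trifurcating root): d1 = 0 by the multiplicity convention
  expect_equal(unname(root_gap_distances(ext)["d1"]), 0)

  # the worked tree extended with a third branching event at age 50
  three <- from_newick("((G2:70,(G1:50,G3:50):20):20,G4:90):10;")
  g <- root_gap_distances(three)     # events at 10, 30, 50
  expect_equal(unname(g), c(20, 40))
})
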