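# Fitch scoring against independent oracles; step bounds; CI/RI.

test_that("hand-checkable Fitch lengths are reproduced", {
  cm <- make_cm(rbind(A = "0", B = "0", C = "1", D = "1"))
  expect_equal(fitch_length(tiny_tree("((A,B),(C,D));"), cm)$length, 1)
  expect_equal(fitch_length(tiny_tree("((A,C),(B,D));"), cm)$length, 2)
  # constant character costs nothing anywhere
  cm0 <- make_cm(rbind(A = "0", B = "0", C = "0", D = "0"))
  expect_equal(fitch_length(tiny_tree("((A,B),(C,D));"), cm0)$length, 0)
  # missing/polymorphic tips take their cheapest resolution: only the
  # fixed 0 vs 1 conflict costs a step
  cmq <- make_cm(rbind(A = "0", B = "?", C = "01", D = "1"))
  expect_equal(fitch_length(tiny_tree("((A,B),(C,D));"), cmq)$length, 1)
  # leaf mismatch is a hard error listing the difference
  expect_error(fitch_length(tiny_tree("((A,B),(C,E));"), cm), "E")
})

test_that("Fitch equals uniform-cost Sankoff on random instances", {
  set.seed(55)
  scheds <- all_topology_schedules(8)
  for (i in 1:200) {
    cells <- random_cells(8, 10, k = sample(2:4, 1),
                          p_missing = 0.15, p_poly = 0.1)
    cm <- make_cm(cells)
    # score the package on a random topology drawn from the enumeration
    idx <- sample.int(length(scheds), 1)
    edge <- all_topologies(8)[[idx]]
    phy <- ape::read.tree(
      text = hadromosaic:::ut_newick(edge, 8, cm$taxa))
    expect_equal(fitch_length(phy, cm)$length,
                 sankoff_length(cm, sched = scheds[[idx]]))
  }
})

test_that("length is invariant under re-rooting and label permutation", {
  set.seed(66)
  for (i in 1:20) {
    cells <- random_cells(8, 12, k = 3, p_missing = 0.2)
    cm <- make_cm(cells)
    tr <- gen_random_tree(8, seed = i, labels = rownames(cells))
    L <- fitch_length(tr, cm)$length
    rooted <- ape::root(tr, sample(tr$tip.label, 1), resolve.root = TRUE)
    expect_equal(fitch_length(rooted, cm)$length, L)
    # rotating children (ladderize) changes nothing
    expect_equal(fitch_length(ape::ladderize(tr), cm)$length, L)
  }
})

test_that("minimum steps solve the state-set cover", {
  expect_equal(min_steps(make_cm(cbind(c(A = "0", B = "1", C = "2")))), 2)
  expect_equal(min_steps(make_cm(cbind(c(A = "0", B = "0")))), 0)
  expect_equal(min_steps(make_cm(cbind(c(A = "?", B = "?", C = "?")))), 0)
  # {0},{01},{1} needs both states; {01},{0},{0} is covered by 0 alone
  expect_equal(min_steps(make_cm(cbind(c(A = "0", B = "01", C = "1")))), 1)
  expect_equal(min_steps(make_cm(cbind(c(A = "01", B = "0", C = "0")))), 0)
})

test_that("step bounds bracket realized lengths and match brute force", {
  set.seed(77)
  scheds6 <- all_topology_schedules(6)
  for (i in 1:100) {
    cells <- random_cells(6, 3, k = sample(2:3, 1),
                          p_missing = 0.15, p_poly = 0.15)
    cm <- make_cm(cells)
    per_tree <- vapply(scheds6, function(s)
      sankoff_steps(s, cm$cells, 6), matrix(numeric(3), 3))
    brute_min <- apply(per_tree, 1, min)
    brute_max <- apply(per_tree, 1, max)
    expect_equal(as.numeric(min_steps(cm)), brute_min)
    expect_equal(as.numeric(max_steps(cm)), brute_max)
  }
  # the fixed-state example: 0,0,0,1,1 over 5 taxa can cost at most 2
  cm5 <- make_cm(cbind(c(a = "0", b = "0", c = "0", d = "1", e = "1")))
  expect_equal(max_steps(cm5), 2)
  expect_equal(min_steps(cm5), 1)
})

test_that("CI and RI follow their closed forms", {
  # two characters with m = 1, g = 2 each; a tree realizing L = 3 gives
  # CI = 2/3 and RI = (4 - 3) / (4 - 2) = 0.5
  cells2 <- cbind(c(A = "0", B = "0", C = "1", D = "1"),
                  c(A = "0", B = "1", C = "0", D = "1"))
  cm2 <- make_cm(cells2)
  idx2 <- ci_ri(cm2, 3)
  expect_equal(idx2$sum_min, 2)
  expect_equal(idx2$sum_max, 4)
  expect_equal(idx2$CI, 2 / 3)
  expect_equal(idx2$RI, 0.5)
  # realized: a homoplasy-free matrix gives CI = RI = 1
  tr <- gen_random_tree(10, seed = 4)
  cm <- evolve_characters(tr, character_sim_spec(
    n_taxa = 10, n_char = 60, p_change = 0.04, missing_frac = 0, seed = 9))
  L <- fitch_length(tr, cm)$length
  idx <- ci_ri(cm, L)
  expect_true(idx$CI > 0 && idx$CI <= 1)
  expect_true(is.na(idx$RI) || (idx$RI > 0 && idx$RI <= 1))
  expect_gte(L, idx$sum_min)
  expect_lte(L, idx$sum_max)
  expect_error(ci_ri(cm, idx$sum_min - 1), "below the minimum")
  # L equal to the bound: perfect consistency
  cmp <- make_cm(rbind(A = "0", B = "0", C = "1", D = "1"))
  perfect <- ci_ri(cmp, 1)
  expect_equal(perfect$CI, 1)
  expect_equal(perfect$RI, 1)
  # no informative variation: RI undefined
  cmu <- make_cm(rbind(A = "0", B = "1", C = "0", D = "0"))
  expect_true(is.na(ci_ri(cmu, 1)$RI))
})

test_that("uninformative characters can be excluded from the indices", {
  cells <- cbind(c(A = "0", B = "0", C = "1", D = "1"),  # informative
                 c(A = "0", B = "1", C = "0", D = "0"))  # autapomorphy
  cm <- make_cm(cells)
  all_in <- ci_ri(cm, 2)
  excl <- ci_ri(cm, 2, exclude_uninformative = TRUE)
  expect_equal(all_in$CI, 2 / 2)
  expect_equal(excl$CI, 1 / 1)
  expect_equal(excl$sum_min, 1)
})

test_that("scores agree with the reference parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(91)
  for (i in 1:20) {
    cells <- matrix(as.character(sample(0:2, 8 * 12, TRUE)), 8, 12)
    rownames(cells) <- sprintf("t%02d", 1:8)
    cells[sample(length(cells), 12)] <- "?"
    cm <- make_cm(cells)
    tr <- gen_random_tree(8, seed = 700 + i, labels = rownames(cells))
    pd <- phangorn::phyDat(cells, type = "USER", levels = c("0", "1", "2"),
                           ambiguity = "?")
    expect_equal(fitch_length(tr, cm)$length,
                 phangorn::parsimony(tr, pd, method = "fitch"),
                 ignore_attr = TRUE)
  }
})
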