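# Consensus, bootstrap, Bremer, synapomorphies.

test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- tiny_tree("((A,B),C,(D,E));")
  t2 <- tiny_tree("((A,C),B,(D,E));")
  sc <- strict_consensus(list(t1, t2))
  expect_equal(tree_bipartitions(sc), "4,5")  # D,E in sorted taxa A..E
  # consensus of copies of one tree is that tree
  t3 <- gen_random_tree(7, seed = 1)
  sc3 <- strict_consensus(list(t3, t3, t3))
  expect_setequal(tree_bipartitions(sc3), tree_bipartitions(t3))
  expect_error(strict_consensus(list(t1, gen_random_tree(5, seed = 2))),
               "leaf set")
})

test_that("consensus bipartitions equal set-operation oracles", {
  set.seed(88)
  for (i in 1:50) {
    n <- sample(6:9, 1)
    trees <- lapply(1:2, function(j) gen_random_tree(n, seed = 1000 * i + j))
    taxa <- sort(trees[[1]]$tip.label)
    oracle <- intersect(tree_bipartitions(trees[[1]], taxa),
                        tree_bipartitions(trees[[2]], taxa))
    got <- tree_bipartitions(strict_consensus(trees), taxa)
    expect_setequal(got, oracle)
  }
})

test_that("consensus agrees with the reference implementation", {
  skip_if_not_installed("ape")
  set.seed(97)
  for (i in 1:20) {
    trees <- lapply(1:4, function(j) gen_random_tree(8, seed = 300 * i + j))
    taxa <- sort(trees[[1]]$tip.label)
    ref_strict <- ape::consensus(trees, p = 1)
    expect_setequal(tree_bipartitions(strict_consensus(trees), taxa),
                    tree_bipartitions(ref_strict, taxa))
    ref_maj <- ape::consensus(trees, p = 0.5)
    expect_setequal(tree_bipartitions(majority_consensus(trees), taxa),
                    tree_bipartitions(ref_maj, taxa))
  }
})

test_that("majority rule uses a strict > threshold and reports frequencies", {
  one <- gen_random_tree(6, seed = 3)
  m1 <- majority_consensus(list(one))
  expect_setequal(tree_bipartitions(m1), tree_bipartitions(one))
  expect_true(all(m1$node.label %in% c("", "100.0")))
  # a clade in 2 of 3 trees survives at 66.7%
  ta <- tiny_tree("((A,B),(C,D),E);")
  tb <- tiny_tree("((A,B),(C,E),D);")
  tc <- tiny_tree("((A,C),(B,D),E);")
  m <- majority_consensus(list(ta, tb, tc))
  # {A,B} is keyed by its complement side {C,D,E} (tip 1 = A excluded)
  expect_true("3,4,5" %in% tree_bipartitions(m))
  expect_true("66.7" %in% m$node.label)
  # exactly half (2 of 4) is excluded
  m4 <- majority_consensus(list(ta, ta, tc, tc))
  expect_false("3,4,5" %in% tree_bipartitions(m4))
  expect_error(majority_consensus(list(ta), threshold = 0.4), "threshold")
})

test_that("majority-rule output is a valid tree on random tree sets", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(6:8, 1)
    k <- sample(3:5, 1)
    trees <- lapply(seq_len(k), function(j)
      gen_random_tree(n, seed = 7000 * i + j))
    m <- majority_consensus(trees)
    # a phylo that ape can re-serialize, with all tips, and with pairwise
    # compatible splits (clusters nest or are disjoint)
    expect_s3_class(m, "phylo")
    expect_equal(sort(m$tip.label), sort(trees[[1]]$tip.label))
    keys <- tree_bipartitions(m)
    sets <- lapply(strsplit(keys, ","), as.integer)
    if (length(sets) > 1) {
      for (a in seq_along(sets)) for (b in seq_along(sets)) {
        if (a >= b) next
        inter <- length(intersect(sets[[a]], sets[[b]]))
        expect_true(inter == 0 ||
                    inter == min(length(sets[[a]]), length(sets[[b]])))
      }
    }
  }
})

test_that("strict consensus splits are a subset of majority splits", {
  set.seed(44)
  for (i in 1:20) {
    trees <- lapply(1:3, function(j) gen_random_tree(7, seed = 90 * i + j))
    taxa <- sort(trees[[1]]$tip.label)
    s <- tree_bipartitions(strict_consensus(trees), taxa)
    m <- tree_bipartitions(majority_consensus(trees), taxa)
    expect_true(all(s %in% m))
  }
})

test_that("bootstrap resamples to size, is deterministic, stays in [0,100]", {
  tr <- gen_random_tree(7, seed = 5)
  cm <- evolve_characters(tr, character_sim_spec(
    n_taxa = 7, n_char = 30, p_change = 0.1, missing_frac = 0, seed = 6))
  cfg <- search_config(replicates = 1, hold_per_replicate = 5,
                       max_trees = 20)
  b1 <- bootstrap_support(cm, replicates = 15, seed = 9, config = cfg)
  b2 <- bootstrap_support(cm, replicates = 15, seed = 9, config = cfg)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_true(all(b1$support >= 0 & b1$support <= 100))
  expect_equal(attr(b1, "provenance")$replicates, 15)
})

test_that("strong zero-homoplasy clades earn near-complete bootstrap", {
  tr <- gen_random_tree(7, seed = 11)
  # every internal edge supported by several compatible characters:
  # replicate the clean characters of the generating tree
  base <- evolve_characters(tr, character_sim_spec(
    n_taxa = 7, n_char = 40, p_change = 0.08, missing_frac = 0, seed = 12))
  steps <- fitch_length(tr, base)$steps
  clean <- base$cells[, steps == min_steps(base) & steps > 0, drop = FALSE]
  cm <- character_matrix(clean[, rep(seq_len(ncol(clean)), 3)])
  bs <- bootstrap_support(cm, replicates = 50, seed = 13,
                          config = search_config(replicates = 1,
                                                 hold_per_replicate = 5,
                                                 max_trees = 20))
  taxa <- sort(cm$taxa)
  true_splits <- tree_bipartitions(tr, taxa)
  sup <- bs$support[match(true_splits, bs$split)]
  sup[is.na(sup)] <- 0
  expect_true(all(sup >= 90))
})

test_that("a single separating character gives Bremer decay one", {
  # one informative character splitting {A,B} from {C,D,E}
  cells <- cbind(c(A = "1", B = "1", C = "0", D = "0", E = "0"))
  cm <- character_matrix(cells)
  res <- heuristic_search(cm, search_config(replicates = 2,
                                            hold_per_replicate = 20,
                                            seed = 2))
  expect_equal(res$length, 1)
  bd <- bremer_decay(cm, res, k_max = 2,
                     config = search_config(hold_per_replicate = 300,
                                            max_trees = 400))
  # the {A,B}|{C,D,E} bipartition is keyed by the side excluding taxon A
  ab <- bd[bd$clade %in% c("A B", "C D E"), ]
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$decay, 1)
  # exhaustive oracle: some tree of length 2 lacks the {A,B} clade
  lens <- exhaustive_lengths(cm)
  expect_equal(min(lens), 1)
  expect_true(any(lens == 2))
})

test_that("decay values are positive and clades in the MPT strict consensus", {
  tr <- gen_random_tree(7, seed = 21)
  cm <- evolve_characters(tr, character_sim_spec(
    n_taxa = 7, n_char = 25, p_change = 0.1, missing_frac = 0, seed = 22))
  res <- heuristic_search(cm, search_config(replicates = 2,
                                            hold_per_replicate = 30,
                                            seed = 3))
  bd <- bremer_decay(cm, res, k_max = 2,
                     config = search_config(hold_per_replicate = 500,
                                            max_trees = 800))
  expect_true(all(bd$decay >= 1))
  sc_keys <- tree_bipartitions(strict_consensus(res), sort(cm$taxa))
  # decay is only reported for clades surviving the MPT strict consensus
  for (key in bd$split) expect_true(key %in% sc_keys)
})

test_that("unambiguous synapomorphies sit on the expected stem", {
  # outgroup O state 0; clade (A,B) fixed 1; others 0; clean tree
  tr <- tiny_tree("(O,(C,(D,(A,B))));")
  cells <- cbind(c(O = "0", A = "1", B = "1", C = "0", D = "0"),
                 c(O = "0", A = "0", B = "0", C = "0", D = "0"))
  cm <- character_matrix(cells)
  syn <- map_synapomorphies(tr, cm, outgroup = "O")
  expect_equal(nrow(syn), 1L)
  expect_setequal(strsplit(syn$clade, " ")[[1]], c("A", "B"))
  expect_equal(syn$character, 1L)
  expect_equal(syn$from, "0")
  expect_equal(syn$to, "1")
})

test_that("every reported change occurs in every minimum reconstruction", {
  set.seed(202)
  for (i in 1:15) {
    cells <- random_cells(6, 8, k = 2, p_missing = 0.1)
    cm <- make_cm(cells)
    tr <- gen_random_tree(6, seed = 500 + i, labels = cm$taxa)
    syn <- map_synapomorphies(tr, cm, outgroup = cm$taxa[1])
    if (!nrow(syn)) next
    ut <- hadromosaic:::phylo_to_ut(tr, cm$taxa)
    sched <- topo_schedule(ut$edge, 6)
    for (r in seq_len(nrow(syn))) {
      j <- syn$character[r]
      rec <- all_min_reconstructions(sched, cm$cells, j, 6)
      clade_tips <- sort(match(strsplit(syn$clade[r], " ")[[1]], cm$taxa))
      # locate the tree node whose tip cluster matches the reported clade
      clus <- lapply(sched$order, function(v) {
        below <- function(x) if (x <= 6) x else
          unlist(lapply(sched$children[[x]], below))
        sort(below(v))
      })
      # for tip branches the "clade" is the tip itself
      vnode <- if (length(clade_tips) == 1L) clade_tips
        else sched$order[[which(vapply(clus, identical, logical(1),
                                       y = clade_tips))]]
      pnode <- NA_integer_
      for (v in sched$order) if (vnode %in% sched$children[[v]]) pnode <- v
      for (rr in seq_len(nrow(rec$assignments))) {
        asg <- as.list(stats::setNames(
          as.character(unlist(rec$assignments[rr, ])),
          as.character(rec$nodes)))
        state_of <- function(node, parent_state) {
          if (node > 6) return(asg[[as.character(node)]])
          s <- cm$cells[node, j]
          ts <- if (s == "?") rec$states else strsplit(s, "")[[1]]
          if (parent_state %in% ts) parent_state else ts[1]
        }
        ps <- if (is.na(pnode)) NA else asg[[as.character(pnode)]]
        if (is.na(pnode)) next
        cs <- state_of(vnode, ps)
        expect_false(identical(ps, cs))
      }
    }
  }
})

test_that("support annotations survive a Newick round trip", {
  tr <- gen_random_tree(7, seed = 5)
  cm <- evolve_characters(tr, character_sim_spec(
    n_taxa = 7, n_char = 30, p_change = 0.1, missing_frac = 0, seed = 6))
  bs <- bootstrap_support(cm, replicates = 10, seed = 9,
                          config = search_config(replicates = 1,
                                                 hold_per_replicate = 5,
                                                 max_trees = 20))
  ann <- annotate_support(tr, bs)
  f <- tempfile()
  write_newick(ann, f)
  back <- read_newick(f)[[1]]
  taxa <- sort(tr$tip.label)
  ut <- hadromosaic:::phylo_to_ut(back, taxa)
  # labels re-attach to the same bipartitions after parsing
  sp <- hadromosaic:::ut_splits(ut$edge, ut$ntip)
  expect_setequal(sp$keys, tree_bipartitions(tr, taxa))
})
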