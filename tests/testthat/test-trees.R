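four_leaf_set <- function(newicks) {
  tree_sample_set(lapply(newicks, function(x) ape::read.tree(text = x)))
}

test_that("sampling-schedule arithmetic counts trees as floor + initial", {
  expect_equal(expected_sample_count(run_schedule(5e6, 100, TRUE)), 50001)
  expect_equal(expected_sample_count(run_schedule(100, 100, TRUE)), 2)
  expect_equal(expected_sample_count(run_schedule(999, 100, FALSE)), 9)
  expect_error(run_schedule(100, 0), "sample_every")
  # linear in generations at fixed stride
  counts <- vapply(c(1e4, 2e4, 3e4), function(g) {
    expected_sample_count(run_schedule(g, 100, FALSE))
  }, numeric(1))
  expect_equal(diff(counts), c(100, 100))
})

test_that("burn-in discards floor(fraction * n) leading trees", {
  base <- "((A,B),(C,D));"
  alt <- "((A,C),(B,D));"
  ts <- four_leaf_set(c(alt, base, base, base))
  kept <- apply_burnin(ts, 0.25)
  expect_equal(length(kept), 3L)
  # the discarded tree is the first one: all retained equal `base`
  expect_true(all(vapply(kept$trees, function(t) {
    phangorn::RF.dist(t, ape::read.tree(text = base)) == 0
  }, logical(1))))

  expect_equal(length(apply_burnin(ts, 0)), 4L)
  expect_equal(length(apply_burnin(tree_sample_set(list()), 0.25)), 0L)

  # the published-run arithmetic: 50,001 trees, 25% burn-in -> 37,501 retained
  expect_equal(50001 - floor(0.25 * 50001), 37501)
  big <- gen_tree_samples(tree_sim_spec("((A,B),(C,D),(E,F));", 11, 0, seed = 1))
  expect_equal(length(apply_burnin(big, 0.25)), 11 - floor(0.25 * 11))
})

test_that("bipartition frequencies equal exhaustive counts", {
  ts3 <- four_leaf_set(rep("((A,B),(C,D));", 3))
  bt3 <- bipartition_frequencies(ts3)
  expect_equal(nrow(bt3), 1L)
  expect_equal(bt3$split, "A,B")
  expect_equal(bt3$frequency, 1.0)

  mixed <- four_leaf_set(c("((A,B),(C,D));", "((A,B),(C,D));", "((A,C),(B,D));"))
  btm <- bipartition_frequencies(mixed)
  expect_equal(btm$frequency[btm$split == "A,B"], 2 / 3)
  expect_equal(btm$frequency[btm$split == "A,C"], 1 / 3)

  single <- four_leaf_set("((A,B),(C,D));")
  expect_equal(nrow(bipartition_frequencies(single)), 1L)  # n - 3 = 1

  # random five-leaf samples against the monophyly-based oracle
  set.seed(31)
  for (rep in 1:4) {
    trees <- replicate(8, ape::rtree(5, rooted = FALSE, br = NULL), simplify = FALSE)
    for (i in seq_along(trees)) trees[[i]]$tip.label <- sample(LETTERS[1:5])
    ts <- tree_sample_set(trees)
    bt <- bipartition_frequencies(ts)
    oracle <- oracle_split_frequencies(ts$trees, ts$leaf_set)
    expect_equal(length(oracle), nrow(bt))
    for (key in names(oracle)) {
      expect_equal(bt$frequency[bt$split == key], oracle[[key]], info = key)
    }
  }
})

test_that("each tree contributes n-3 splits at 1/n_trees multiples", {
  ts <- gen_tree_samples(tree_sim_spec("(((A,B),(C,D)),(E,(F,(G,H))));", 10, 0.5, seed = 4))
  bt <- bipartition_frequencies(ts)
  expect_equal(sum(bt$count), 10 * (8 - 3))
  expect_true(all(abs(bt$frequency * 10 - round(bt$frequency * 10)) < 1e-9))
})

test_that("majority-rule consensus keeps strict-majority splits with supports", {
  ident <- four_leaf_set(rep("((A,B),(C,D));", 5))
  cons <- majority_rule_consensus(bipartition_frequencies(ident))
  expect_true(all(cons$supports$support == 1.0))
  expect_equal(phangorn::RF.dist(cons$tree, ape::read.tree(text = "((A,B),(C,D));")), 0)

  mixed <- four_leaf_set(c("((A,B),(C,D));", "((A,B),(C,D));", "((A,C),(B,D));"))
  cm <- majority_rule_consensus(bipartition_frequencies(mixed))
  expect_equal(cm$supports$split, "A,B")
  expect_equal(cm$supports$support, 2 / 3, tolerance = 1e-9)

  # 50/50 with a strict threshold collapses to a star
  tie <- four_leaf_set(c("((A,B),(C,D));", "((A,C),(B,D));"))
  ct <- majority_rule_consensus(bipartition_frequencies(tie))
  expect_equal(nrow(ct$supports), 0L)
  expect_equal(ct$tree$Nnode, 1L)

  expect_error(majority_rule_consensus(bipartition_frequencies(tie), threshold = 0.4),
               ">= 0.5")
})

test_that("consensus is idempotent and matches the ape cross-check", {
  set.seed(17)
  trees <- replicate(9, ape::rtree(6, rooted = FALSE, br = NULL), simplify = FALSE)
  for (i in seq_along(trees)) trees[[i]]$tip.label <- paste0("t", 1:6)
  ts <- tree_sample_set(trees)
  cons <- majority_rule_consensus(bipartition_frequencies(ts))

  ape_cons <- ape::consensus(ts$trees, p = 0.5)
  expect_equal(phangorn::RF.dist(ape::unroot(cons$tree), ape::unroot(ape_cons)), 0)

  rep_set <- tree_sample_set(rep(list(cons$tree), 4))
  again <- majority_rule_consensus(bipartition_frequencies(rep_set))
  expect_equal(phangorn::RF.dist(ape::unroot(again$tree), ape::unroot(cons$tree)), 0)
  expect_true(all(again$supports$support == 1.0))
})

test_that("ASDSF matches hand-computed two-run standard deviations", {
  run_a <- four_leaf_set(rep("((A,B),(C,D));", 5))
  expect_equal(asdsf(run_a, run_a), 0)

  run_b <- four_leaf_set(c(rep("((A,B),(C,D));", 4), "((A,C),(B,D));"))
  # split AB|CD: sd(1.0, 0.8); split AC|BD: sd(0.0, 0.2)
  expected <- mean(c(stats::sd(c(1.0, 0.8)), stats::sd(c(0.0, 0.2))))
  expect_equal(asdsf(run_a, run_b), expected, tolerance = 1e-12)
  expect_equal(asdsf(run_b, run_a), asdsf(run_a, run_b))

  # below min_freq nothing qualifies
  expect_equal(asdsf(run_a, run_b, min_freq = 0.9), stats::sd(c(1.0, 0.8)))
  run_c <- four_leaf_set("((A,B),(C,E));")
  expect_error(asdsf(run_a, run_c), "leaf sets")
})

test_that("neighbor joining is exact on additive matrices", {
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(dm)
  expect_equal(phangorn::RF.dist(tr, ape::read.tree(text = "((A,B),(C,D));")), 0)
  # additive recovery of the generating branch lengths
  tip_edge <- function(tree, tip) tree$edge.length[tree$edge[, 2] == match(tip, tree$tip.label)]
  expect_equal(tip_edge(tr, "A"), 1)
  expect_equal(tip_edge(tr, "B"), 2)
  expect_equal(tip_edge(tr, "C"), 3)
  expect_equal(tip_edge(tr, "D"), 4)
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], dm,
               ignore_attr = TRUE)

  # random additive matrices from random trees, 5-8 taxa
  set.seed(23)
  for (k in 1:12) {
    n <- sample(5:8, 1)
    true_tree <- ape::rtree(n, rooted = FALSE)
    dmat <- ape::cophenetic.phylo(true_tree)
    rec <- nj_tree(dmat)
    expect_equal(phangorn::RF.dist(ape::unroot(true_tree), rec), 0)
  }

  # taxon order never changes the unrooted topology
  perm <- sample(LETTERS[1:4])
  tr2 <- nj_tree(dm[perm, perm])
  expect_equal(phangorn::RF.dist(tr, tr2), 0)

  bad <- dm; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
})

test_that("origin assignment reads the sister group off the rooted tree", {
  tree <- ape::read.tree(text = "(((e1,e2),(p1,p2)),(c1,c2));")
  labels <- c(e1 = "rhodophyta", e2 = "rhodophyta",
              p1 = "proteobacteria", p2 = "proteobacteria",
              c1 = "cyanobacteria", c2 = "cyanobacteria")
  call <- assign_origin(tree, labels, "rhodophyta")
  expect_equal(call$inferred_donor, "proteobacteria")

  nested <- ape::read.tree(text = "((c1,(c2,(e1,e2))),(p1,(p2,a1)));")
  labels2 <- c(labels, a1 = "archaea")
  call2 <- assign_origin(nested, labels2, "rhodophyta")
  expect_equal(call2$inferred_donor, "cyanobacteria")

  no_prok <- ape::read.tree(text = "((e1,e2),(g1,g2));")
  expect_error(assign_origin(no_prok, c(e1 = "rhodophyta", e2 = "rhodophyta",
                                        g1 = "glaucophyta", g2 = "glaucophyta"),
                             "rhodophyta"),
               "prokaryote")
})

test_that("origin support aggregates donors over a tree sample", {
  t1 <- "(((e1,e2),(p1,p2)),(c1,c2));"
  t2 <- "(((e1,e2),(c1,c2)),(p1,p2));"
  labels <- c(e1 = "rhodophyta", e2 = "rhodophyta",
              p1 = "proteobacteria", p2 = "proteobacteria",
              c1 = "cyanobacteria", c2 = "cyanobacteria")
  ts <- four_leaf_set(c(t1, t1, t1, t2))
  call <- origin_support(ts, labels, "rhodophyta")
  expect_equal(call$inferred_donor, "proteobacteria")
  expect_equal(call$support, 0.75)
})
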