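test_that("edge-weight update follows the additive and floor branches", {
  expect_equal(updateWeights(5, 4, 2),
               c(d_pi = 3L, d_im = 2L, d_in = 1L))
  expect_equal(updateWeights(2, 2, 3),
               c(d_pi = 1L, d_im = 1L, d_in = 1L))  # floor branch
  expect_equal(updateWeights(1, 1, 1),
               c(d_pi = 1L, d_im = 0L, d_in = 0L))  # degenerate zero edges
})

test_that("update is additive whenever the floor is not taken", {
  set.seed(21)
  for (i in 1:100) {
    dpm <- sample.int(10L, 1L)
    dpn <- sample.int(10L, 1L)
    dmn <- sample.int(10L, 1L)
    w <- updateWeights(dpm, dpn, dmn)
    if (max(dpm - dmn, dpn - dmn) >= 1L) {
      expect_equal(w[["d_pi"]] + w[["d_im"]], dpm)
      expect_equal(w[["d_pi"]] + w[["d_in"]], dpn)
    }
    expect_gte(w[["d_pi"]], 1L)
  }
})

# distance matrix whose genotype sequences realise given pairwise distances
.dm_from_seqs <- function(seqs, root = names(seqs)[1]) {
  tab <- collapseGenotypes(
    data.frame(id = names(seqs), seq = unname(seqs), abundance = 1L), root)
  buildDistanceMatrix(tab)
}

test_that("a chain with no sister pairs is left unchanged", {
  seqs <- c(r = "AAAAAA", a = "AAAAAT", b = "AAAATT")
  tr <- make_tree("r a 1", "a b 1", root = "r",
                  sequences = seqs)
  out <- insertUnobservedNodes(tr, .dm_from_seqs(seqs))
  expect_identical(treeEdges(out), treeEdges(tr))
})

test_that("close sisters get an inferred ancestor with updated weights", {
  # d(p,m)=5, d(p,n)=4, d(m,n)=2: expect U1 with weights (3, 2, 1)
  p <- strrep("A", 10)
  m <- "TTTTTAAAAA"  # sites 1-5 mutated: d(p,m) = 5
  n <- "TTTGAAAAAA"  # sites 1-4 mutated (site 4 to G): d(p,n) = 4, d(m,n) = 2
  seqs <- c(p = p, m = m, n = n)
  dm <- .dm_from_seqs(seqs)
  expect_equal(dm@raw["p", "m"], 5L)
  expect_equal(dm@raw["p", "n"], 4L)
  expect_equal(dm@raw["m", "n"], 2L)
  tr <- make_tree("p m 5", "p n 4", root = "p", sequences = seqs)
  out <- insertUnobservedNodes(tr, dm)
  expect_true("U1" %in% nodeLabels(out))
  ed <- treeEdges(out)
  expect_equal(ed$weight[ed$parent == "p" & ed$child == "U1"], 3L)
  expect_equal(ed$weight[ed$parent == "U1" & ed$child == "m"], 2L)
  expect_equal(ed$weight[ed$parent == "U1" & ed$child == "n"], 1L)
  # the inferred ancestor's parsimony sequence sits between p and the pair
  sq <- nodeSequences(out)
  expect_equal(sq[["U1"]], "TTTAAAAAAA")
  expect_false(out@nodes$observed[out@nodes$label == "U1"])
  expect_equal(abundances(out)[["U1"]], 0L)
})

test_that("distant sisters trigger no insertion", {
  # d(m,n) greater than both parent edges
  seqs <- c(p = "AAAAAA", m = "TTAAAA", n = "AATTAA")  # pm 2, pn 2, mn 4
  tr <- make_tree("p m 2", "p n 2", root = "p", sequences = seqs)
  out <- insertUnobservedNodes(tr, .dm_from_seqs(seqs))
  expect_identical(treeEdges(out), treeEdges(tr))
})

test_that("insertion preserves observed nodes and their abundances", {
  set.seed(33)
  for (trial in 1:15) {
    sim <- simulateLineage(easyRegime(simConfig(seed = trial + 700,
                                                rootLength = 400,
                                                maxGenerations = 4)))
    rec <- sim@records
    tab <- collapseGenotypes(rec, "root")
    dm <- buildDistanceMatrix(tab)
    g <- buildLineageGraph(dm, abundances(tab), "root")
    tr <- setTreeSequences(buildTree(g),
                           stats::setNames(tab@seq, tab@label))
    out <- insertUnobservedNodes(tr, dm)
    obs0 <- abundances(tr)[nodeLabels(tr, observedOnly = TRUE)]
    obs1 <- abundances(out)[nodeLabels(out, observedOnly = TRUE)]
    expect_equal(sort(names(obs1)), sort(names(obs0)))
    expect_equal(obs1[names(obs0)], obs0)
    # idempotence at the fixed point
    again <- insertUnobservedNodes(out, dm)
    expect_identical(treeEdges(again), treeEdges(out))
  }
})

test_that("a star tree is already at minimum depth", {
  seqs <- c(r = "AAAA", a = "TAAA", b = "ATAA", c = "AATA")
  tr <- make_tree("r a 1", "r b 1", "r c 1", root = "r", sequences = seqs)
  out <- reduceDepth(tr, .dm_from_seqs(seqs))
  expect_identical(treeEdges(out), treeEdges(tr))
})

test_that("a cost-conserving depth-reducing reattachment is accepted", {
  # chain r -> a -> b where b is as close to r as to a: moving b under r
  # keeps the cost and lowers the depth from 2 to 1
  seqs <- c(r = "AAAAAA", a = "TTAAAA", b = "TAAAAA")
  dm <- .dm_from_seqs(seqs)
  expect_equal(dm@raw["r", "a"], 2L)
  expect_equal(dm@raw["a", "b"], 1L)
  expect_equal(dm@raw["r", "b"], 1L)
  tr <- make_tree("r a 2", "a b 1", root = "r", sequences = seqs)
  out <- reduceDepth(tr, dm)
  expect_equal(treeDepth(out), 1L)
  expect_equal(treeCost(out), treeCost(tr))
  expect_equal(parentOf(out, "b"), "r")
})

test_that("a cost-increasing or depth-neutral move is rejected", {
  # moving b under r would reduce depth but increase cost: reject
  seqs <- c(r = "AAAAAA", a = "TAAAAA", b = "TTTAAA")
  dm <- .dm_from_seqs(seqs)  # r-a 1, a-b 2, r-b 3
  tr <- make_tree("r a 1", "a b 2", root = "r", sequences = seqs)
  out <- reduceDepth(tr, dm)
  expect_identical(treeEdges(out), treeEdges(tr))
})

test_that("depth reduction is monotone in depth and cost and idempotent", {
  set.seed(44)
  for (trial in 1:15) {
    n <- sample(5:15, 1L)
    seqs <- stats::setNames(
      unique(replicate(n, random_sequence(40L))),
      sprintf("n%d", seq_len(n)))
    n <- length(seqs)
    tr <- random_tree(n, labels = names(seqs))
    tr <- setTreeSequences(tr, seqs)
    # weights consistent with the sequences so cost arithmetic is real
    dm <- .dm_from_seqs(seqs)
    ed <- treeEdges(tr)
    ed$weight <- dm@raw[cbind(ed$parent, ed$child)]
    tr <- LineageTree(ed, rootLabel(tr), abundance = abundances(tr),
                      sequences = seqs)
    out <- reduceDepth(tr, dm)
    expect_lte(treeDepth(out), treeDepth(tr))
    expect_lte(treeCost(out), treeCost(tr))
    expect_setequal(nodeLabels(out), nodeLabels(tr))
    again <- reduceDepth(out, dm)
    expect_identical(treeEdges(again), treeEdges(out))
  }
})
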