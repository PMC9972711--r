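# trees with sequences attached for the ancestral metrics
.seq_tree <- function(..., root, seqLen = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- make_tree(..., root = root)
  sq <- stats::setNames(
    vapply(nodeLabels(tr), function(x) random_sequence(seqLen), ""),
    nodeLabels(tr))
  setTreeSequences(tr, sq)
}

test_that("all four metrics vanish on identical trees", {
  set.seed(61)
  tr <- .seq_tree("r a 1", "a b 2", "r c 1", "c d 1", root = "r")
  rep <- compareTrees(tr, tr)
  expect_equal(rep@gedTree, 0L)
  expect_equal(rep@gedPath, 0L)
  expect_equal(rep@gedPathNoUnobserved, 0L)
  expect_equal(rep@mrca, 0)
  expect_equal(rep@coar, 0)
})

test_that("one extra leaf costs two edits; one moved leaf costs two", {
  t1 <- make_tree("r a 1", "a b 1", root = "r")
  t2 <- make_tree("r a 1", "a b 1", "a x 1", root = "r")
  expect_equal(gedTree(t1, t2), 2L)  # node + edge insertion
  expect_equal(gedTree(t2, t1), 2L)  # symmetric
  t3 <- make_tree("r a 1", "a b 1", "r x 1", root = "r")
  expect_equal(gedTree(t2, t3), 2L)  # edge deletion + insertion
  expect_equal(exhaustive_ged(t1, t2), 2L)
  expect_equal(exhaustive_ged(t2, t3), 2L)
})

test_that("exact GED matches the exhaustive edit-script oracle", {
  set.seed(72)
  for (trial in 1:40) {
    n1 <- sample(2:6, 1L)
    n2 <- sample(2:6, 1L)
    shared <- sprintf("s%d", 1:6)
    t1 <- random_tree(n1, labels = sample(shared, n1))
    t2 <- random_tree(n2, labels = sample(shared, n2))
    expect_equal(gedTree(t1, t2), exhaustive_ged(t1, t2),
                 info = sprintf("trial %d", trial))
    expect_equal(gedTree(t1, t2), gedTree(t2, t1))
  }
})

test_that("exact GED refuses oversized trees and the bound can be raised", {
  t1 <- random_tree(14L)
  expect_error(gedTree(t1, t1), "gedPath")
  expect_equal(gedTree(t1, t1, maxNodes = 14L), 0L)
})

test_that("path GED: shared-leaf edit, absent leaves, zero iff identical paths", {
  t1 <- make_tree("r a 1", "a x 1", root = "r")
  t2 <- make_tree("r x 1", root = "r")
  expect_equal(gedPath(t1, t2), 1L)  # delete "a" from r->a->x
  expect_equal(gedPath(t2, t1), 1L)

  # leaf y with 3 nodes below the root in t1, absent from t2
  t3 <- make_tree("r a 1", "a b 1", "b y 1", "r x 1", root = "r")
  t4 <- make_tree("r x 1", root = "r")
  expect_equal(gedPath(t3, t4), 3L)

  t5 <- make_tree("r a 1", "a b 2", root = "r")
  expect_equal(gedPath(t5, t5), 0L)
})

test_that("path GED token edit distance agrees with an adist oracle", {
  set.seed(83)
  for (trial in 1:25) {
    labs <- sprintf("s%d", 1:8)
    t1 <- random_tree(sample(3:8, 1L), labels = sample(labs))
    t2 <- random_tree(sample(3:8, 1L), labels = sample(labs))
    oracle <- 0L
    for (leaf in union(leafLabels(t1), leafLabels(t2))) {
      in1 <- leaf %in% nodeLabels(t1)
      in2 <- leaf %in% nodeLabels(t2)
      if (in1 && in2)
        oracle <- oracle + adist_levenshtein(pathToRoot(t1, leaf),
                                             pathToRoot(t2, leaf))
      else if (in1) oracle <- oracle + length(pathToRoot(t1, leaf)) - 1L
      else oracle <- oracle + length(pathToRoot(t2, leaf)) - 1L
    }
    expect_equal(gedPath(t1, t2), oracle, info = sprintf("trial %d", trial))
  }
})

test_that("skipping unobserved nodes removes them from every path", {
  sq <- c(r = "AAAA", a = "TAAA", b = "TTAA", U1 = "TAAA")
  t1 <- make_tree("r U1 1", "U1 a 1", "U1 b 2", root = "r",
                  abundance = c(r = 1L, U1 = 0L, a = 1L, b = 1L),
                  observed = c(U1 = FALSE), sequences = sq)
  t2 <- make_tree("r a 1", "r b 2", root = "r",
                  sequences = sq[c("r", "a", "b")])
  expect_equal(gedPath(t1, t2, skipUnobserved = TRUE), 0L)
  expect_gt(gedPath(t1, t2), 0L)
})

test_that("MRCA distance averages ancestor disagreement over node pairs", {
  # two 4-node trees identical except one inferred-ancestor sequence
  # differing at 2 of 20 positions; that ancestor is the MRCA for exactly
  # 1 of the 3 observed pairs: (0 + 0 + 2/20) / 3 = 1/30
  base <- strrep("A", 20)
  sq1 <- c(r = base, i = paste0("TT", strrep("A", 18)),
           x = paste0("TTTT", strrep("A", 16)),
           y = paste0("TTGG", strrep("A", 16)))
  sq2 <- sq1
  sq2[["i"]] <- paste0("CC", strrep("A", 18))  # 2/20 different
  mk <- function(sq) make_tree("r i 2", "i x 2", "i y 2", root = "r",
                               abundance = c(r = 1L, i = 0L, x = 1L, y = 1L),
                               observed = c(i = FALSE), sequences = sq)
  t1 <- mk(sq1)
  t2 <- mk(sq2)
  expect_equal(mrcaDistance(t1, t2), 1 / 30)

  # with the ancestor observed in both trees it joins the pair set: the
  # three pairs whose MRCA it is each contribute 2/20 out of 6 pairs
  mk2 <- function(sq) make_tree("r i 2", "i x 2", "i y 2", root = "r",
                                sequences = sq)
  expect_equal(mrcaDistance(mk2(sq1), mk2(sq2)), 3 * (2 / 20) / 6)
})

test_that("MRCA is zero when shared ancestors carry identical sequences", {
  set.seed(91)
  tr <- .seq_tree("r a 2", "a b 1", "r c 3", root = "r")
  expect_equal(mrcaDistance(tr, tr), 0)
})

test_that("MRCA never decreases when an internal sequence is perturbed more", {
  set.seed(95)
  tr <- .seq_tree("r i 1", "i x 1", "i y 1", "r z 1", root = "r",
                  seqLen = 30L)
  perturb <- function(tree, label, k) {
    s <- strsplit(nodeSequences(tree)[[label]], "")[[1]]
    for (pos in seq_len(k)) s[pos] <- setdiff(c("A","C","G","T"), s[pos])[1]
    sq <- nodeSequences(tree)
    sq[label] <- paste(s, collapse = "")
    setTreeSequences(tree, sq)
  }
  vals <- vapply(0:30, function(k) mrcaDistance(tr, perturb(tr, "i", k)),
                 numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("path alignment scores match hand-computed cases", {
  L <- 30L
  s <- strrep("A", L)
  expect_equal(alignPaths(c(s, s), c(s, s)), 0)
  # shorter path shares both nodes: one gap
  expect_equal(alignPaths(c(s, s), c(s, s, s)), -1)
  # single nodes differing at 3 of 30 positions
  s2 <- paste0("TTT", strrep("A", 27))
  expect_equal(alignPaths(s, s2), -0.1)
  expect_error(alignPaths(s, "AAA"), "equal length")
})

test_that("COAR handles identical trees, extra path nodes and absent leaves", {
  set.seed(103)
  tr <- .seq_tree("r a 1", "a b 1", "r c 1", root = "r")
  expect_equal(coarDistance(tr, tr), 0)

  # t2 has one extra intermediate with the same sequences elsewhere:
  # paths (r,a,b) vs (r,a,m,b) align with one gap -> COAR(b) = 1/4,
  # leaf c matches exactly -> mean over the two leaves
  s <- nodeSequences(tr)
  t2 <- make_tree("r a 1", "a m 1", "m b 1", "r c 1", root = "r",
                  sequences = c(s, m = s[["a"]]))
  expect_equal(coarDistance(tr, t2), mean(c(1 / 4, 0)))

  # a leaf absent from the other tree is the worst case
  t3 <- make_tree("r a 1", "a b 1", root = "r",
                  sequences = s[c("r", "a", "b")])
  onlyLeaf <- make_tree("r z 1", root = "r",
                        sequences = c(r = s[["r"]], z = s[["b"]]))
  expect_equal(coarDistance(onlyLeaf, t3), 1)
})

test_that("MRCA and COAR stay within [0,1] on random tree pairs", {
  set.seed(117)
  for (trial in 1:15) {
    labs <- sprintf("s%d", 1:7)
    sq <- stats::setNames(vapply(1:7, function(i) random_sequence(15L), ""),
                          labs)
    n1 <- sample(3:7, 1L); n2 <- sample(3:7, 1L)
    l1 <- c("s1", sample(labs[-1], n1 - 1L))
    l2 <- c("s1", sample(labs[-1], n2 - 1L))
    t1 <- setTreeSequences(random_tree(n1, labels = l1), sq[l1])
    t2 <- setTreeSequences(random_tree(n2, labels = l2), sq[l2])
    if (length(intersect(l1, l2)) < 2L) next
    m <- mrcaDistance(t1, t2)
    cc <- coarDistance(t1, t2)
    expect_gte(m, 0); expect_lte(m, 1)
    expect_gte(cc, 0); expect_lte(cc, 1)
    expect_equal(m, mrcaDistance(t2, t1))
  }
})

test_that("metrics demand sequences and enough shared nodes", {
  t1 <- make_tree("r a 1", root = "r")
  expect_error(mrcaDistance(t1, t1), "lacking a sequence|fewer than two")
  sq <- c(r = "AAAA", a = "TAAA")
  t1s <- setTreeSequences(t1, sq)
  t2 <- make_tree("r b 1", root = "r",
                  sequences = c(r = "AAAA", b = "TTAA"))
  expect_error(mrcaDistance(t1s, t2), "fewer than two")
})
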