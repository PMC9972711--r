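test_that("hamming distance counts mismatches with the gap and N rules", {
  expect_equal(hammingDistance("ACGT", "ACGT"), 0L)
  expect_equal(hammingDistance("ACGT", "ACGA"), 1L)
  expect_equal(hammingDistance("AC-T", "ACGT"), 1L)  # gap vs base
  expect_equal(hammingDistance("A--T", "A--T"), 0L)  # shared gaps match
  expect_equal(hammingDistance("ANGT", "ANGT"), 1L)  # N never matches N
  expect_equal(hammingDistance("NNGT", "NNGT"), 2L)
  expect_equal(hammingDistance("ANGT", "AAGT"), 1L)  # N vs base
  expect_error(hammingDistance("ACG", "ACGT"), "length")
})

test_that("hamming is a metric on equal-length strings", {
  set.seed(7)
  alph <- c("A", "C", "G", "T", "-")
  for (i in 1:50) {
    L <- sample(3:20, 1)
    x <- paste(sample(alph, L, TRUE), collapse = "")
    y <- paste(sample(alph, L, TRUE), collapse = "")
    z <- paste(sample(alph, L, TRUE), collapse = "")
    dxy <- hammingDistance(x, y)
    expect_gte(dxy, 0L)
    expect_equal(hammingDistance(x, x), 0L)
    expect_equal(dxy, hammingDistance(y, x))
    expect_lte(hammingDistance(x, z), dxy + hammingDistance(y, z))
  }
})

test_that("alignment mode 'none' is the identity on equal-length input", {
  rec <- data.frame(id = c("a", "b"), seq = c("ACGT", "ACGA"),
                    abundance = 1L)
  expect_identical(alignSequences(rec, "none"), rec)
  rec$seq[2] <- "ACG"
  expect_error(alignSequences(rec, "none"), "equal-length")
})

test_that("builtin aligner equalises lengths and conserves content", {
  rec <- data.frame(id = c("a", "b"), seq = c("ACGT", "ACT"),
                    abundance = 1L)
  out <- alignSequences(rec, "builtin")
  expect_equal(length(unique(nchar(out$seq))), 1L)
  expect_equal(gsub("-", "", out$seq), rec$seq)
})

test_that("builtin aligner leaves indel-free clonal variants ungapped", {
  set.seed(5)
  sim <- simulateLineage(easyRegime(simConfig(seed = 5, rootLength = 80,
                                              maxGenerations = 3)))
  rec <- sim@records[seq_len(min(12, nrow(sim@records))), ]
  out <- alignSequences(rec, "builtin")
  expect_false(any(grepl("-", out$seq)))
  expect_equal(out$seq, rec$seq)
})

test_that("distance matrix agrees with a brute-force double loop", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(2:15, 1)
    L <- 30L
    seqs <- unique(replicate(n, random_sequence(L)))
    tab <- collapseGenotypes(
      data.frame(id = sprintf("g%d", seq_along(seqs)), seq = seqs,
                 abundance = 1L),
      rootId = "g1")
    dm <- buildDistanceMatrix(tab)
    for (i in seq_along(tab@label)) for (j in seq_along(tab@label)) {
      expect_equal(dm@raw[i, j],
                   hammingDistance(tab@seq[i], tab@seq[j]))
    }
    expect_true(all(dm@normalised == dm@raw / L))
    expect_equal(dm@raw, t(dm@raw))
    expect_true(all(diag(dm@raw) == 0L))
  }
})

test_that("single genotype gives a 1x1 zero matrix", {
  tab <- collapseGenotypes(
    data.frame(id = "a", seq = "ACGT", abundance = 3L), "a")
  dm <- buildDistanceMatrix(tab)
  expect_equal(dim(dm@raw), c(1L, 1L))
  expect_equal(dm@raw[1, 1], 0L)
})

test_that("graph construction: complete graph, delta pruning, disconnection", {
  seqs <- c(r = "AAAA", a = "AAAT", b = "AATT", c = "TTTT")
  tab <- collapseGenotypes(
    data.frame(id = names(seqs), seq = unname(seqs), abundance = 1L), "r")
  dm <- buildDistanceMatrix(tab)
  ab <- abundances(tab)

  g <- buildLineageGraph(dm, ab, "r")
  expect_equal(sum(!is.na(g@weight[upper.tri(g@weight)])), 6L)

  # pairwise distances: r-a 1, a-b 1, b-c 2, r-b 2, a-c 3, r-c 4
  g2 <- buildLineageGraph(dm, ab, "r", delta = 2)
  w2 <- g2@weight
  expect_true(is.na(w2["a", "c"]))
  expect_true(is.na(w2["r", "c"]))
  expect_equal(w2["b", "c"], 2L)

  expect_error(buildLineageGraph(dm, ab, "r", delta = 0),
               "disconnects.*smallest connecting delta is 2")
})

test_that("literal below-delta pruning is available behind its flag", {
  seqs <- c(r = "AAAAAA", a = "TTTTAA", b = "TTTTTT")
  # r-a 4, a-b 2, r-b 6
  tab <- collapseGenotypes(
    data.frame(id = names(seqs), seq = unname(seqs), abundance = 1L), "r")
  g <- buildLineageGraph(buildDistanceMatrix(tab), abundances(tab), "r",
                         delta = 3, deltaBelow = TRUE)
  expect_true(is.na(g@weight["a", "b"]))  # the short edge is removed
  expect_equal(g@weight["r", "a"], 4L)
  expect_equal(g@weight["r", "b"], 6L)
})

test_that("external aligner conserves content and equalises lengths", {
  skip_if_not(nzchar(Sys.which("mafft")), "mafft binary not on PATH")
  rec <- data.frame(id = c("a", "b", "c"),
                    seq = c("ACGTACGTACGT", "ACGTACGT", "ACGTTACGTACGT"),
                    abundance = 1L)
  out <- alignSequences(rec, "external")
  expect_equal(length(unique(nchar(out$seq))), 1L)
  expect_equal(gsub("-", "", out$seq), rec$seq)
  expect_error(alignSequences(rec, "external", binary = "no-such-aligner"),
               "not found")
})

test_that("distance matrix TSV export carries labels and values", {
  tab <- collapseGenotypes(
    data.frame(id = c("a", "b"), seq = c("AAAA", "AATT"), abundance = 1L),
    "a")
  txt <- writeDistanceMatrix(buildDistanceMatrix(tab))
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(length(lines), 3L)
  expect_equal(strsplit(lines[2], "\t")[[1]], c("a", "0", "2"))
})
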