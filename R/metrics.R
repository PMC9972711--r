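# Node identity keys used to match nodes across two trees: observed
# genotypes match by label; unobserved (inferred) nodes match by sequence
# when one is attached, otherwise they never match.
.identity_keys <- function(tree, tag) {
  nd <- tree@nodes
  sq <- tree@sequences
  vapply(seq_len(nrow(nd)), function(i) {
    lab <- nd$label[i]
    if (nd$observed[i]) return(paste0("L:", lab))
    if (lab %in% names(sq) && !is.na(sq[[lab]]))
      return(paste0("S:", sq[[lab]]))
    paste0("X:", tag, ":", lab)
  }, "")
}

#' Exact tree-based graph edit distance
#'
#' Minimum total number of unit-cost edit operations (node insertion,
#' deletion, substitution; directed edge insertion, deletion) transforming
#' one rooted lineage tree into another. Nodes match across trees by
#' genotype label; unobserved nodes match by sequence equality when
#' sequences are attached and are otherwise always distinct. The search is
#' an exact depth-first branch-and-bound over injective node assignments
#' with an admissible identity-multiset lower bound: near-identical trees
#' resolve immediately, while very dissimilar large trees are worst-case
#' exponential, so inputs beyond \code{maxNodes} are refused rather than
#' approximated (use [gedPath()] there, or raise the bound knowingly).
#'
#' @param t1,t2 [LineageTree-class] objects with a shared labeling scheme.
#' @param maxNodes refuse larger trees (default 12).
#' @return non-negative integer; 0 iff the trees are label-isomorphic.
#' @export
gedTree <- function(t1, t2, maxNodes = 12L) {
  n1 <- nrow(t1@nodes)
  n2 <- nrow(t2@nodes)
  if (max(n1, n2) > maxNodes)
    stop(sprintf(
      "tree has %d nodes, over the exact-GED bound of %d; use gedPath() ",
      max(n1, n2), maxNodes),
      "or raise maxNodes if the trees are near-identical", call. = FALSE)
  id1 <- .identity_keys(t1, "t1")
  id2 <- .identity_keys(t2, "t2")
  e1 <- t1@edges
  e2 <- t2@edges
  lab1 <- t1@nodes$label
  lab2 <- t2@nodes$label
  # order t1 nodes pre-order so parent edges are checkable early
  ord <- match(preorderLabels(t1), lab1)
  id1 <- id1[ord]
  lab1 <- lab1[ord]
  e1i <- cbind(match(e1$parent, lab1), match(e1$child, lab1))
  e2key <- paste(match(e2$parent, lab2), match(e2$child, lab2))
  best <- Inf

  # admissible lower bound on completing a partial assignment: identities
  # in the remaining multisets that cannot find an identical partner each
  # cost at least 1 (substitution, deletion or insertion)
  lb_nodes <- function(rem1, rem2) {
    i1 <- sort(id1[rem1])
    i2 <- sort(id2[rem2])
    common <- 0L
    a <- 1L; b <- 1L
    while (a <= length(i1) && b <= length(i2)) {
      if (i1[a] == i2[b]) { common <- common + 1L; a <- a + 1L; b <- b + 1L }
      else if (i1[a] < i2[b]) a <- a + 1L else b <- b + 1L
    }
    max(length(i1), length(i2)) - common
  }

  assign2 <- integer(n1)  # index in t2 per t1 node (0 = deleted)
  used2 <- logical(n2)
  e2p <- match(e2$parent, lab2)
  e2c <- match(e2$child, lab2)

  rec <- function(k, cost, matched) {
    if (k > n1) {
      total <- cost + sum(!used2) + (nrow(e2) - length(matched))
      if (total < best) best <<- total
      return(invisible())
    }
    if (cost + lb_nodes(seq.int(k, n1), which(!used2)) >= best)
      return(invisible())
    # candidate targets: identical identity first, then the rest, then drop
    free <- which(!used2)
    samev <- free[id2[free] == id1[k]]
    others <- setdiff(free, samev)
    for (v in c(samev, others, 0L)) {
      nodeCost <- if (v == 0L) 1L else if (id2[v] == id1[k]) 0L else 1L
      edgeCost <- 0L
      newMatched <- matched
      inc <- which((e1i[, 1L] == k & e1i[, 2L] < k) |
                   (e1i[, 2L] == k & e1i[, 1L] < k))
      for (ei in inc) {
        a <- e1i[ei, 1L]; b <- e1i[ei, 2L]
        fa <- if (a == k) v else assign2[a]
        fb <- if (b == k) v else assign2[b]
        if (fa == 0L || fb == 0L) { edgeCost <- edgeCost + 1L; next }
        key <- paste(fa, fb)
        if (key %in% e2key) newMatched <- c(newMatched, key)
        else edgeCost <- edgeCost + 1L
      }
      assign2[k] <<- v
      if (v > 0L) used2[v] <<- TRUE
      # t2 edges with both endpoints used but unmatched can never match
      dead <- sum(used2[e2p] & used2[e2c] &
                  !(paste(e2p, e2c) %in% newMatched))
      newCost <- cost + nodeCost + edgeCost
      if (newCost + dead < best)
        rec(k + 1L, newCost, newMatched)
      if (v > 0L) used2[v] <<- FALSE
      assign2[k] <<- 0L
    }
    invisible()
  }
  rec(1L, 0L, character(0))
  as.integer(best)
}

# Unit-cost Levenshtein distance over token vectors
.token_levenshtein <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (!la) return(lb)
  if (!lb) return(la)
  prev <- 0:lb
  for (i in seq_len(la)) {
    cur <- integer(lb + 1L)
    cur[1L] <- i
    for (j in seq_len(lb)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[lb + 1L]
}

.path_tokens <- function(tree, label, ids, skipUnobserved) {
  p <- pathToRoot(tree, label)
  tok <- ids[match(p, tree@nodes$label)]
  if (skipUnobserved) {
    obs <- tree@nodes$observed[match(p, tree@nodes$label)]
    tok <- tok[obs]
  }
  tok
}

#' Path-based graph edit distance
#'
#' Compares the two trees one root-to-leaf path at a time: for every leaf
#' present in both trees, the unit-cost edit distance between its
#' root-to-node label paths; a leaf absent from the other tree contributes
#' its full path length (nodes below the root). The result is the sum over
#' the union of the two trees' leaves (each leaf counted once). More
#' stringent than the tree-based distance: every path difference is
#' penalised in each path it touches.
#'
#' @param t1,t2 [LineageTree-class] objects.
#' @param skipUnobserved drop unobserved nodes from every path before
#'   comparison (useful when inferred ancestors dominate the differences).
#' @return non-negative integer; 0 iff every shared leaf has an identical
#'   path in both trees and no leaf is missing.
#' @export
gedPath <- function(t1, t2, skipUnobserved = FALSE) {
  id1 <- .identity_keys(t1, "a")
  id2 <- .identity_keys(t2, "b")
  leaves <- union(leafLabels(t1), leafLabels(t2))
  total <- 0L
  for (leaf in leaves) {
    in1 <- leaf %in% t1@nodes$label
    in2 <- leaf %in% t2@nodes$label
    if (in1 && in2) {
      p1 <- .path_tokens(t1, leaf, id1, skipUnobserved)
      p2 <- .path_tokens(t2, leaf, id2, skipUnobserved)
      total <- total + .token_levenshtein(p1, p2)
    } else if (in1) {
      total <- total + length(.path_tokens(t1, leaf, id1,
                                           skipUnobserved)) - 1L
    } else {
      total <- total + length(.path_tokens(t2, leaf, id2,
                                           skipUnobserved)) - 1L
    }
  }
  as.integer(total)
}

.require_sequences <- function(tree, labels, what) {
  sq <- tree@sequences
  miss <- labels[!(labels %in% names(sq)) | is.na(sq[labels])]
  if (length(miss))
    stop(sprintf("%s: node(s) lacking a sequence: %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

.mrca_of <- function(tree, a, b) {
  pa <- pathToRoot(tree, a)
  pb <- pathToRoot(tree, b)
  common <- pa[pa %in% pb]
  common[length(common)]
}

#' MRCA ancestral-reconstruction distance
#'
#' For every unordered pair of observed genotypes present in both trees,
#' finds the pair's most recent common ancestor in each tree and takes the
#' hamming distance between the two ancestors' sequences, normalised by
#' the longer sequence; the metric is the average over all pairs. 0 means
#' every pairwise ancestor was reconstructed with an identical sequence
#' (perfect recent-ancestor reconstruction); 1 is the worst case. Because
#' observed genotypes may be internal, all observed node pairs are used,
#' not only leaves.
#'
#' @param t1,t2 [LineageTree-class] objects with sequences attached to
#'   every node (inferred ancestors included).
#' @return number in [0, 1].
#' @export
mrcaDistance <- function(t1, t2) {
  shared <- intersect(nodeLabels(t1, observedOnly = TRUE),
                      nodeLabels(t2, observedOnly = TRUE))
  if (length(shared) < 2L)
    stop("fewer than two observed nodes shared between the trees",
         call. = FALSE)
  .require_sequences(t1, t1@nodes$label, "mrcaDistance (tree 1)")
  .require_sequences(t2, t2@nodes$label, "mrcaDistance (tree 2)")
  prs <- utils::combn(sort(shared), 2L)
  vals <- apply(prs, 2L, function(p) {
    a1 <- .mrca_of(t1, p[1L], p[2L])
    a2 <- .mrca_of(t2, p[1L], p[2L])
    s1 <- t1@sequences[[a1]]
    s2 <- t2@sequences[[a2]]
    as.numeric(hammingDistance2(s1, s2)) / max(nchar(s1), nchar(s2))
  })
  mean(vals)
}

# hamming between possibly unequal-length sequences: mismatches over the
# shared prefix plus the length difference (used only by the MRCA metric,
# whose normalisation is max length; with a shared alignment lengths are
# equal and this reduces to hammingDistance)
hammingDistance2 <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == lb) return(hammingDistance(a, b))
  l <- min(la, lb)
  hammingDistance(substr(a, 1L, l), substr(b, 1L, l)) + abs(la - lb)
}

#' Needleman-Wunsch alignment score of two root-to-node paths
#'
#' Global alignment over path positions (each position is a tree node
#' carrying a sequence): aligning node u with node v scores minus their
#' normalised hamming distance (0 for identical sequences, -1 for maximal
#' disagreement); every gapped position scores -1. The optimal score is 0
#' for identical paths and bounded below by minus the longer path length.
#'
#' @param p1,p2 character vectors of node sequences along each path
#'   (root first), all of one length.
#' @return the maximal total alignment score (<= 0).
#' @export
alignPaths <- function(p1, p2) {
  L <- unique(c(nchar(p1), nchar(p2)))
  if (length(L) != 1L)
    stop("path sequences must all have equal length", call. = FALSE)
  n1 <- length(p1); n2 <- length(p2)
  gap <- -1
  S <- matrix(0, n1 + 1L, n2 + 1L)
  S[, 1L] <- gap * (0:n1)
  S[1L, ] <- gap * (0:n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    sub <- -hammingDistance(p1[i], p2[j]) / L
    S[i + 1L, j + 1L] <- max(S[i, j] + sub,
                             S[i, j + 1L] + gap,
                             S[i + 1L, j] + gap)
  }
  S[n1 + 1L, n2 + 1L]
}

#' COAR ancestral-reconstruction distance
#'
#' Correctness of ancestral reconstruction over whole evolutionary paths:
#' for each leaf of the first (reference) tree that exists in the second,
#' its root-to-leaf sequence path is aligned ([alignPaths()]) against
#' every root-to-leaf path of the second tree containing that node; the
#' best (maximum) score, negated and normalised by the longer of the two
#' path lengths, is that leaf's contribution (score ties resolve to the
#' longer candidate path). Leaves absent from the second tree contribute
#' the worst case 1. The metric is the mean over the reference tree's
#' leaves: 0 for perfectly reconstructed paths, 1 at worst.
#'
#' @param t1,t2 [LineageTree-class] objects with sequences on every node.
#' @return number in [0, 1].
#' @export
coarDistance <- function(t1, t2) {
  .require_sequences(t1, t1@nodes$label, "coarDistance (tree 1)")
  .require_sequences(t2, t2@nodes$label, "coarDistance (tree 2)")
  lv1 <- leafLabels(t1)
  contrib <- vapply(lv1, function(leaf) {
    if (!(leaf %in% t2@nodes$label)) return(1)
    p1 <- pathToRoot(t1, leaf)
    s1 <- unname(t1@sequences[p1])
    cands <- leafLabels(t2)
    cands <- cands[vapply(cands, function(l2)
      leaf %in% pathToRoot(t2, l2), logical(1))]
    bestScore <- -Inf
    bestLen <- 0L
    for (l2 in cands) {
      p2 <- pathToRoot(t2, l2)
      s2 <- unname(t2@sequences[p2])
      sc <- alignPaths(s1, s2)
      if (sc > bestScore || (sc == bestScore && length(p2) > bestLen)) {
        bestScore <- sc
        bestLen <- length(p2)
      }
    }
    -bestScore / max(length(p1), bestLen)
  }, numeric(1))
  mean(contrib)
}

#' Compare two lineage trees with all four metrics
#'
#' @param t1,t2 [LineageTree-class] objects; sequences must be attached on
#'   every node for the MRCA and COAR metrics.
#' @param gedMaxNodes exact-GED size bound passed to [gedTree()].
#' @return a [MetricReport-class].
#' @export
compareTrees <- function(t1, t2, gedMaxNodes = 12L) {
  new("MetricReport",
      gedTree = gedTree(t1, t2, maxNodes = gedMaxNodes),
      gedPath = gedPath(t1, t2),
      gedPathNoUnobserved = gedPath(t1, t2, skipUnobserved = TRUE),
      mrca = mrcaDistance(t1, t2),
      coar = coarDistance(t1, t2))
}
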