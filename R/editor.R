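#' Edge-weight update when interposing an unobserved ancestor
#'
#' When sister nodes m and n under parent p are closer to each other than
#' to p, a missing common ancestor i is interposed. Its edge weights are
#' \deqn{d_{pi} = \max(d_{pm} - d_{mn},\; d_{pn} - d_{mn},\; 1)}
#' \deqn{d_{im} = d_{pm} - d_{pi}, \quad d_{in} = d_{pn} - d_{pi}}
#' The floor of 1 keeps the new ancestor a distinct genotype; when it is
#' taken, the additive identities d_pi + d_im = d_pm (and likewise for n)
#' no longer hold.
#'
#' @param dpm,dpn integer edge weights from p to the sisters m and n.
#' @param dmn integer hamming distance between the sisters.
#' @return named integer vector (d_pi, d_im, d_in).
#' @examples
#' updateWeights(5, 4, 2)  # d_pi 3, d_im 2, d_in 1
#' updateWeights(2, 2, 3)  # floor branch: d_pi 1
#' @export
updateWeights <- function(dpm, dpn, dmn) {
  dpi <- max(dpm - dmn, dpn - dmn, 1L)
  c(d_pi = as.integer(dpi),
    d_im = as.integer(dpm - dpi),
    d_in = as.integer(dpn - dpi))
}

# Distance between two tree nodes: from the distance matrix when both are
# covered, else from attached sequences; NA when neither source applies.
.node_dist <- function(tree, matrix, a, b) {
  if (!is.null(matrix) && a %in% matrix@label && b %in% matrix@label)
    return(matrix@raw[a, b])
  sq <- tree@sequences
  if (a %in% names(sq) && b %in% names(sq) &&
      !is.na(sq[[a]]) && !is.na(sq[[b]]))
    return(hammingDistance(sq[[a]], sq[[b]]))
  NA_integer_
}

# Parsimony sequence for an inferred ancestor of sisters m, n under p:
# per column, the symbol the sisters share, else the parent's symbol.
.reconstruct_sequence <- function(sp, sm, sn) {
  cm <- charToRaw(sm)
  cn <- charToRaw(sn)
  cp <- charToRaw(sp)
  out <- cp
  agree <- cm == cn
  out[agree] <- cm[agree]
  rawToChar(out)
}

.next_u_label <- function(tree) {
  u <- grep("^U[0-9]+$", tree@nodes$label, value = TRUE)
  k <- if (length(u)) max(as.integer(sub("^U", "", u))) + 1L else 1L
  sprintf("U%d", k)
}

.set_edge <- function(edges, parent, child, weight) {
  rbind(edges, data.frame(parent = parent, child = child,
                          weight = as.integer(weight),
                          stringsAsFactors = FALSE))
}

#' Insert unobserved internal nodes
#'
#' Scans the tree in pre-order for sister pairs that are at least as close
#' to each other as to their parent (trigger: d_mn <= min(d_pm, d_pn),
#' the strictest reading), evidence of an unsampled common ancestor. Each
#' trigger interposes a new unobserved node (labels "U1", "U2", ... in
#' insertion order, abundance 0) with weights from [updateWeights()]; at
#' most one insertion per parent per pass, and passes repeat until no pair
#' triggers. If the tree carries sequences, the new ancestor receives a
#' parsimony-reconstructed sequence (sister consensus, parent symbol at
#' disagreeing columns). A zero-weight edge to an unobserved child merges
#' the child into the new node; an observed child keeps its weight-0 edge
#' (it is a distinct sampled genotype). Pairs under an unobserved parent
#' with only those two children are skipped: that parent already is their
#' inferred ancestor.
#'
#' @param tree a [LineageTree-class].
#' @param matrix a [DistanceMatrix-class] covering all observed labels.
#' @return the edited tree; observed nodes and abundances are unchanged.
#' @export
insertUnobservedNodes <- function(tree, matrix) {
  missing <- setdiff(tree@nodes$label[tree@nodes$observed], matrix@label)
  if (length(missing))
    stop(sprintf("distance matrix missing label(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  repeat {
    changed <- FALSE
    for (p in preorderLabels(tree)) {
      kids <- sort(childrenOf(tree, p), method = "radix")
      if (length(kids) < 2L) next
      pObserved <- tree@nodes$observed[match(p, tree@nodes$label)]
      if (!pObserved && length(kids) == 2L) next
      done <- FALSE
      for (i in seq_len(length(kids) - 1L)) {
        for (j in seq.int(i + 1L, length(kids))) {
          m <- kids[i]; n <- kids[j]
          dmn <- .node_dist(tree, matrix, m, n)
          if (is.na(dmn)) next
          ed <- tree@edges
          dpm <- ed$weight[ed$child == m]
          dpn <- ed$weight[ed$child == n]
          if (dmn > min(dpm, dpn)) next
          tree <- .apply_insertion(tree, p, m, n, dpm, dpn, dmn)
          changed <- TRUE
          done <- TRUE
          break
        }
        if (done) break
      }
    }
    if (!changed) break
  }
  validObject(tree)
  tree
}

.apply_insertion <- function(tree, p, m, n, dpm, dpn, dmn) {
  w <- updateWeights(dpm, dpn, dmn)
  u <- .next_u_label(tree)
  ed <- tree@edges[!(tree@edges$parent == p &
                     tree@edges$child %in% c(m, n)), , drop = FALSE]
  ed <- .set_edge(ed, p, u, w[["d_pi"]])
  nodes <- rbind(tree@nodes, data.frame(label = u, abundance = 0L,
                                        observed = FALSE,
                                        stringsAsFactors = FALSE))
  sq <- tree@sequences
  if (all(c(p, m, n) %in% names(sq))) {
    sq[u] <- .reconstruct_sequence(sq[[p]], sq[[m]], sq[[n]])
  }
  obs <- stats::setNames(tree@nodes$observed, tree@nodes$label)
  for (child in c(m, n)) {
    wuc <- if (child == m) w[["d_im"]] else w[["d_in"]]
    if (wuc == 0L && !obs[[child]]) {
      # merge the unobserved child into the new ancestor
      ed$parent[ed$parent == child] <- u
      ed <- ed[ed$child != child, , drop = FALSE]
      nodes <- nodes[nodes$label != child, , drop = FALSE]
      sq <- sq[setdiff(names(sq), child)]
    } else {
      ed <- .set_edge(ed, u, child, wuc)
    }
  }
  new("LineageTree", nodes = nodes, edges = ed, sequences = sq,
      rootLabel = tree@rootLabel)
}

#' Depth-reducing detach/reattach editing
#'
#' Greedy post-processing toward a more parsimonious (shallower) tree:
#' every non-root node is considered in pre-order as the root of a subtree
#' to detach; reattachment targets are scanned in pre-order over the nodes
#' outside that subtree. A move is accepted iff the overall tree depth
#' strictly decreases and the total cost does not increase, where the new
#' edge weight is the hamming distance between the new parent and the
#' moved node (distance matrix for observed pairs, attached sequences
#' otherwise). First improving move is applied and the tree rescanned,
#' until no move helps. Moves that would leave an unobserved node with
#' fewer than two children are rejected.
#'
#' @param tree a [LineageTree-class].
#' @param matrix a [DistanceMatrix-class].
#' @return the edited tree: same node set, depth never larger, cost never
#'   larger.
#' @export
reduceDepth <- function(tree, matrix) {
  repeat {
    depth0 <- treeDepth(tree)
    cost0 <- treeCost(tree)
    improved <- FALSE
    obs <- stats::setNames(tree@nodes$observed, tree@nodes$label)
    for (cand in setdiff(preorderLabels(tree), tree@rootLabel)) {
      sub <- subtreeLabels(tree, cand)
      oldParent <- parentOf(tree, cand)
      if (!obs[[oldParent]] &&
          sum(tree@edges$parent == oldParent) <= 2L) next
      oldW <- tree@edges$weight[tree@edges$child == cand]
      for (target in setdiff(preorderLabels(tree), c(sub, oldParent))) {
        wNew <- .node_dist(tree, matrix, target, cand)
        if (is.na(wNew)) next
        if (cost0 - oldW + wNew > cost0) next
        ed <- tree@edges
        i <- which(ed$child == cand)
        ed$parent[i] <- target
        ed$weight[i] <- as.integer(wNew)
        moved <- new("LineageTree", nodes = tree@nodes, edges = ed,
                     sequences = tree@sequences,
                     rootLabel = tree@rootLabel)
        if (treeDepth(moved) < depth0) {
          tree <- moved
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  validObject(tree)
  tree
}
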