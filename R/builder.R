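#' Grow the lineage tree by abundance-aware minimum spanning tree
#'
#' Modified Prim's algorithm with a hierarchical bi-objective: starting
#' from the root, repeatedly attach the out-of-tree genotype reachable by
#' the lowest edge weight (primary objective: minimise total mutation
#' count); among equal-weight candidates the genotype with the highest
#' abundance is attached first (secondary objective: abundant genotypes
#' are more likely progenitors); remaining ties fall back to lexicographic
#' (attachment node, candidate node) order, so the result is deterministic.
#'
#' The default frontier semantics re-examines every tree-to-outside edge at
#' each step (lazy multi-insertion), which guarantees the minimum spanning
#' cost. \code{singleInsertion = TRUE} switches to a strict
#' insert-each-node-once priority queue whose entries are never updated; it
#' is kept for compatibility and can miss cheaper attachments discovered
#' after a node first enters the queue.
#'
#' @param graph a [LineageGraph-class] (connected).
#' @param useAbundance apply the secondary abundance objective.
#' @param singleInsertion use the insert-once queue variant.
#' @return a [LineageTree-class] over all genotypes, rooted at the graph's
#'   root, with the graph's edge weights.
#' @export
buildTree <- function(graph, useAbundance = TRUE, singleInsertion = FALSE) {
  labels <- graph@label
  n <- length(labels)
  w <- graph@weight
  ab <- stats::setNames(graph@abundance, labels)
  root <- graph@rootLabel
  inTree <- stats::setNames(rep(FALSE, n), labels)
  inTree[root] <- TRUE
  edges <- data.frame(parent = character(), child = character(),
                      weight = integer(), stringsAsFactors = FALSE)
  if (n > 1L) {
    if (!singleInsertion) {
      for (step in seq_len(n - 1L)) {
        ti <- which(inTree)
        oi <- which(!inTree)
        sub <- w[ti, oi, drop = FALSE]
        if (all(is.na(sub)))
          stop("genotype graph is disconnected; cannot span all genotypes",
               call. = FALSE)
        best <- .pick_candidate(
          weight = as.vector(sub),
          from = rep(labels[ti], times = length(oi)),
          node = rep(labels[oi], each = length(ti)),
          abundance = rep(ab[labels[oi]], each = length(ti)),
          fromAbundance = rep(ab[labels[ti]], times = length(oi)),
          useAbundance = useAbundance)
        edges <- rbind(edges, data.frame(
          parent = best$from, child = best$node, weight = best$weight,
          stringsAsFactors = FALSE))
        inTree[best$node] <- TRUE
      }
    } else {
      queue <- data.frame(weight = integer(), from = character(),
                          node = character(), stringsAsFactors = FALSE)
      enqueue <- function(u) {
        nb <- labels[!inTree & !is.na(w[u, labels])]
        nb <- setdiff(nb, queue$node)      # each node enters only once
        if (length(nb))
          queue <<- rbind(queue, data.frame(
            weight = w[u, nb], from = u, node = nb,
            stringsAsFactors = FALSE))
      }
      enqueue(root)
      while (any(!inTree)) {
        live <- !inTree[queue$node]
        queue <- queue[live, , drop = FALSE]
        if (!nrow(queue))
          stop("genotype graph is disconnected; cannot span all genotypes",
               call. = FALSE)
        best <- .pick_candidate(queue$weight, queue$from, queue$node,
                                ab[queue$node], ab[queue$from],
                                useAbundance)
        queue <- queue[queue$node != best$node, , drop = FALSE]
        edges <- rbind(edges, data.frame(
          parent = best$from, child = best$node, weight = best$weight,
          stringsAsFactors = FALSE))
        inTree[best$node] <- TRUE
        enqueue(best$node)
      }
    }
  }
  LineageTree(edges = edges, rootLabel = root, abundance = ab,
              observed = stats::setNames(rep(TRUE, n), labels))
}

# Hierarchical selection: min weight, then (if enabled) max candidate
# abundance, then max attachment-side abundance (equal-weight edges to the
# same candidate attach under the more abundant tree node), then
# lexicographic (from, node). Returns one candidate.
.pick_candidate <- function(weight, from, node, abundance, fromAbundance,
                            useAbundance) {
  keep <- !is.na(weight)
  weight <- weight[keep]; from <- from[keep]; node <- node[keep]
  abundance <- abundance[keep]; fromAbundance <- fromAbundance[keep]
  sel <- weight == min(weight)
  if (useAbundance) {
    sel <- sel & abundance == max(abundance[sel])
    sel <- sel & fromAbundance == max(fromAbundance[sel])
  }
  idx <- which(sel)
  idx <- idx[order(from[idx], node[idx], method = "radix")][1L]
  list(weight = as.integer(weight[idx]), from = from[idx], node = node[idx])
}
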