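#' Construct a LineageTree
#'
#' Low-level constructor used by the builder, the editors, the tree readers
#' and the simulator. Node metadata not supplied defaults to observed with
#' abundance 1, except labels starting with "U" followed by digits when
#' \code{autoUnobserved} is set (the serialization convention for inferred
#' ancestors), which default to unobserved with abundance 0.
#'
#' @param edges data.frame with columns parent, child, weight (a zero-row
#'   data.frame gives a single-node tree).
#' @param rootLabel label of the root.
#' @param abundance named integer vector (labels missing default as above).
#' @param observed named logical vector (same defaulting).
#' @param sequences named character vector of node sequences, or NULL.
#' @param autoUnobserved flag unobserved nodes from the "U<k>" label pattern
#'   plus zero abundance.
#' @return a validated [LineageTree-class].
#' @export
LineageTree <- function(edges, rootLabel, abundance = NULL, observed = NULL,
                        sequences = NULL, autoUnobserved = FALSE) {
  if (nrow(edges)) {
    edges <- data.frame(parent = as.character(edges$parent),
                        child = as.character(edges$child),
                        weight = as.integer(edges$weight),
                        stringsAsFactors = FALSE)
    labels <- unique(c(rootLabel, edges$parent, edges$child))
  } else {
    edges <- data.frame(parent = character(), child = character(),
                        weight = integer(), stringsAsFactors = FALSE)
    labels <- rootLabel
  }
  ab <- rep(1L, length(labels))
  names(ab) <- labels
  if (!is.null(abundance)) ab[names(abundance)] <- as.integer(abundance)
  ob <- rep(TRUE, length(labels))
  names(ob) <- labels
  if (!is.null(observed)) ob[names(observed)] <- observed
  if (autoUnobserved) {
    auto <- grepl("^U[0-9]+$", labels) & ab == 0L
    ob[auto] <- FALSE
  }
  nodes <- data.frame(label = labels, abundance = unname(ab[labels]),
                      observed = unname(ob[labels]),
                      stringsAsFactors = FALSE)
  sq <- if (is.null(sequences)) character(0) else sequences
  new("LineageTree", nodes = nodes, edges = edges,
      sequences = sq, rootLabel = rootLabel)
}

#' @name accessors
#' @title Accessors for lineage objects
#' @param x a [GenotypeTable-class], [LineageGraph-class] or
#'   [LineageTree-class].
#' @return \code{rootLabel}: the root's label; \code{abundances}: a named
#'   integer vector of genotype abundances.
NULL

#' @rdname accessors
#' @export
setMethod("rootLabel", "GenotypeTable", function(x) x@rootLabel)
#' @rdname accessors
#' @export
setMethod("rootLabel", "LineageGraph", function(x) x@rootLabel)
#' @rdname accessors
#' @export
setMethod("rootLabel", "LineageTree", function(x) x@rootLabel)

#' @rdname accessors
#' @export
setMethod("abundances", "GenotypeTable", function(x) {
  stats::setNames(x@abundance, x@label)
})
#' @rdname accessors
#' @export
setMethod("abundances", "LineageGraph", function(x) {
  stats::setNames(x@abundance, x@label)
})
#' @rdname accessors
#' @export
setMethod("abundances", "LineageTree", function(x) {
  stats::setNames(x@nodes$abundance, x@nodes$label)
})

#' Node labels of a lineage tree
#' @param tree a [LineageTree-class].
#' @param observedOnly restrict to observed genotypes.
#' @return character vector of labels.
#' @export
nodeLabels <- function(tree, observedOnly = FALSE) {
  if (observedOnly) tree@nodes$label[tree@nodes$observed] else tree@nodes$label
}

#' Edge table of a lineage tree
#' @param tree a [LineageTree-class].
#' @return data.frame with columns parent, child, weight.
#' @export
treeEdges <- function(tree) tree@edges

#' Node sequences of a lineage tree
#' @param tree a [LineageTree-class].
#' @return named character vector (possibly empty).
#' @export
nodeSequences <- function(tree) tree@sequences

#' Attach sequences to a lineage tree
#' @param tree a [LineageTree-class].
#' @param sequences named character vector covering (at least) all labels
#'   that need sequences; extra names are ignored.
#' @return the tree with sequences set.
#' @export
setTreeSequences <- function(tree, sequences) {
  keep <- intersect(names(sequences), tree@nodes$label)
  tree@sequences <- sequences[keep]
  validObject(tree)
  tree
}

#' Children of a node
#' @param tree a [LineageTree-class].
#' @param label a node label.
#' @return character vector of child labels, in edge order.
#' @export
childrenOf <- function(tree, label) {
  tree@edges$child[tree@edges$parent == label]
}

#' Parent of a node
#' @param tree a [LineageTree-class].
#' @param label a node label.
#' @return the parent label, or NA for the root.
#' @export
parentOf <- function(tree, label) {
  i <- match(label, tree@edges$child)
  if (is.na(i)) NA_character_ else tree@edges$parent[i]
}

#' Leaf labels of a lineage tree
#' @param tree a [LineageTree-class].
#' @return labels of nodes with no children.
#' @export
leafLabels <- function(tree) {
  setdiff(tree@nodes$label, unique(tree@edges$parent))
}

#' Pre-order traversal
#' @param tree a [LineageTree-class].
#' @return node labels in root-first depth-first order (children visited in
#'   edge order).
#' @export
preorderLabels <- function(tree) {
  out <- character(nrow(tree@nodes))
  k <- 0L
  stack <- tree@rootLabel
  while (length(stack)) {
    x <- stack[1L]
    stack <- stack[-1L]
    k <- k + 1L
    out[k] <- x
    stack <- c(childrenOf(tree, x), stack)
  }
  out[seq_len(k)]
}

#' Path from a node up to the root
#' @param tree a [LineageTree-class].
#' @param label a node label.
#' @param rootFirst return the path root-first (default) or node-first.
#' @return character vector of labels along the unique path.
#' @export
pathToRoot <- function(tree, label, rootFirst = TRUE) {
  if (!label %in% tree@nodes$label)
    stop(sprintf("node '%s' not in tree", label))
  p <- label
  while (!is.na(nxt <- parentOf(tree, p[length(p)]))) p <- c(p, nxt)
  if (rootFirst) rev(p) else p
}

#' Labels of the subtree rooted at a node
#' @param tree a [LineageTree-class].
#' @param label a node label.
#' @return labels of the node and all its descendants.
#' @export
subtreeLabels <- function(tree, label) {
  out <- label
  frontier <- label
  while (length(frontier)) {
    kids <- tree@edges$child[tree@edges$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Total cost of a lineage tree
#'
#' Sum of all edge weights: the number of mutations the tree implies. The
#' builder minimises this quantity first.
#'
#' @param tree a [LineageTree-class].
#' @return non-negative integer.
#' @export
#' @rdname treeCost
setMethod("treeCost", "LineageTree", function(tree) {
  as.integer(sum(tree@edges$weight))
})

#' Depth of a lineage tree
#'
#' Maximum number of edges on a root-to-leaf path; 0 for a single node.
#'
#' @param tree a [LineageTree-class].
#' @return non-negative integer.
#' @export
#' @rdname treeDepth
setMethod("treeDepth", "LineageTree", function(tree) {
  if (!nrow(tree@edges)) return(0L)
  depth <- stats::setNames(rep(NA_integer_, nrow(tree@nodes)),
                           tree@nodes$label)
  depth[tree@rootLabel] <- 0L
  frontier <- tree@rootLabel
  while (length(frontier)) {
    kids <- tree@edges$child[tree@edges$parent %in% frontier]
    if (length(kids)) {
      par <- tree@edges$parent[match(kids, tree@edges$child)]
      depth[kids] <- depth[par] + 1L
    }
    frontier <- kids
  }
  max(depth, na.rm = TRUE)
})

setMethod("show", "LineageTree", function(object) {
  nd <- object@nodes
  cat(sprintf(
    "LineageTree: %d nodes (%d observed, %d unobserved), root '%s'\n",
    nrow(nd), sum(nd$observed), sum(!nd$observed), object@rootLabel))
  cat(sprintf("  cost %d, depth %d, %d leaves%s\n",
              treeCost(object), treeDepth(object),
              length(leafLabels(object)),
              if (length(object@sequences)) ", sequences attached" else ""))
})

setMethod("show", "GenotypeTable", function(object) {
  cat(sprintf(
    "GenotypeTable: %d genotypes, alignment length %d, root '%s'\n",
    length(object@label), object@alignmentLength, object@rootLabel))
  cat(sprintf("  total abundance %d\n", sum(object@abundance)))
})

setMethod("show", "LineageGraph", function(object) {
  w <- object@weight
  ne <- sum(!is.na(w[upper.tri(w)]))
  cat(sprintf("LineageGraph: %d genotypes, %d edges%s, root '%s'\n",
              length(object@label), ne,
              if (length(object@delta))
                sprintf(" (delta = %g)", object@delta) else "",
              object@rootLabel))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n")
  cat(sprintf("  GED (tree-based): %d\n", object@gedTree))
  cat(sprintf("  GED (path-based): %d\n", object@gedPath))
  cat(sprintf("  GED (path-based, unobserved removed): %d\n",
              object@gedPathNoUnobserved))
  cat(sprintf("  MRCA: %.6g\n  COAR: %.6g\n", object@mrca, object@coar))
})

setMethod("show", "SimulatedLineage", function(object) {
  cat(sprintf(
    "SimulatedLineage (seed %d): %d true nodes, %d observed records\n",
    object@seed, nrow(object@truth@nodes), nrow(object@records)))
})

#' Coerce a MetricReport to a one-row data.frame
#' @param report a [MetricReport-class].
#' @return data.frame with columns ged_tree, ged_path,
#'   ged_path_no_unobserved, mrca, coar.
#' @export
asMetricRow <- function(report) {
  data.frame(ged_tree = report@gedTree, ged_path = report@gedPath,
             ged_path_no_unobserved = report@gedPathNoUnobserved,
             mrca = report@mrca, coar = report@coar)
}
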