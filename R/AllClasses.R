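#' @import methods
NULL

#' GenotypeTable: deduplicated genotypes with abundances
#'
#' Holds the collapsed set of aligned genotype sequences of one B-cell
#' clonal lineage: each genotype is a class of identical aligned sequences,
#' its abundance the number of input reads that collapsed into it. Exactly
#' one genotype is designated as the root (the inferred unmutated ancestor).
#'
#' @slot label character vector of unique genotype labels.
#' @slot seq character vector of aligned sequences over \{A,C,G,T,N,-\},
#'   all of length \code{alignmentLength}, parallel to \code{label}.
#' @slot abundance integer vector of positive collapsed read counts.
#' @slot rootLabel label of the root genotype.
#' @slot alignmentLength common sequence length.
#'
#' @seealso [collapseGenotypes()], [buildDistanceMatrix()]
#' @export
setClass("GenotypeTable",
  representation(
    label = "character",
    seq = "character",
    abundance = "integer",
    rootLabel = "character",
    alignmentLength = "integer"
  )
)

setValidity("GenotypeTable", function(object) {
  n <- length(object@label)
  if (n == 0L) return("empty genotype table")
  if (anyDuplicated(object@label)) return("genotype labels must be unique")
  if (length(object@seq) != n || length(object@abundance) != n)
    return("label, seq and abundance must have equal length")
  if (sum(object@label == object@rootLabel) != 1L)
    return(sprintf("root label '%s' must match exactly one genotype",
                   object@rootLabel))
  L <- object@alignmentLength
  if (any(nchar(object@seq) != L))
    return("all aligned sequences must have length alignmentLength")
  if (any(grepl("[^ACGTN-]", object@seq)))
    return("sequences restricted to alphabet {A,C,G,T,N,-}")
  if (any(object@abundance < 1L))
    return("genotype abundances must be >= 1")
  if (anyDuplicated(object@seq))
    return("genotypes must have distinct aligned sequences")
  TRUE
})

#' LineageGraph: weighted undirected genotype graph
#'
#' Complete (or delta-pruned) undirected graph over genotypes whose edge
#' weights are raw integer hamming distances on the shared alignment; the
#' input to the spanning-tree builder.
#'
#' @slot label genotype labels, including the root.
#' @slot weight symmetric integer matrix of raw hamming distances;
#'   \code{NA} marks an edge removed by delta pruning.
#' @slot abundance named integer vector of genotype abundances.
#' @slot rootLabel label of the root genotype.
#' @slot delta numeric pruning threshold actually applied (length 0 if none).
#'
#' @seealso [buildLineageGraph()], [buildTree()]
#' @export
setClass("LineageGraph",
  representation(
    label = "character",
    weight = "matrix",
    abundance = "integer",
    rootLabel = "character",
    delta = "numeric"
  )
)

setValidity("LineageGraph", function(object) {
  n <- length(object@label)
  if (!all(dim(object@weight) == c(n, n)))
    return("weight matrix dimensions must match number of labels")
  if (!(object@rootLabel %in% object@label))
    return("root label absent from graph")
  if (length(object@abundance) != n)
    return("abundance vector must be parallel to labels")
  w <- object@weight
  if (!isTRUE(all.equal(w, t(w)))) return("weight matrix must be symmetric")
  if (any(diag(w) != 0, na.rm = TRUE)) return("diagonal must be zero")
  TRUE
})

#' LineageTree: rooted directed B-cell lineage tree
#'
#' The reconstruction result: a rooted arborescence over observed genotypes
#' plus any inferred unobserved ancestors, with integer mutation-count edge
#' weights. Observed genotypes may be internal nodes, as is typical for
#' B-cell lineages. Node sequences are optional until the ancestral-
#' reconstruction metrics need them.
#'
#' @slot nodes data.frame with columns \code{label} (character, unique),
#'   \code{abundance} (integer), \code{observed} (logical).
#' @slot edges data.frame with columns \code{parent}, \code{child}
#'   (character labels) and \code{weight} (non-negative integer).
#' @slot sequences named character vector mapping labels to nucleotide
#'   sequences (possibly gapped); may be empty.
#' @slot rootLabel label of the root node.
#'
#' @seealso [buildTree()], [insertUnobservedNodes()], [reduceDepth()],
#'   [writeLineageTree()]
#' @export
setClass("LineageTree",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    sequences = "character",
    rootLabel = "character"
  )
)

setValidity("LineageTree", function(object) {
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("label", "abundance", "observed") %in% names(nd)))
    return("nodes must have columns label, abundance, observed")
  if (!all(c("parent", "child", "weight") %in% names(ed)))
    return("edges must have columns parent, child, weight")
  if (anyDuplicated(nd$label)) return("node labels must be unique")
  if (!(object@rootLabel %in% nd$label)) return("root label not a node")
  nonroot <- setdiff(nd$label, object@rootLabel)
  if (object@rootLabel %in% ed$child) return("root must have no parent")
  if (anyDuplicated(ed$child)) return("a node has more than one parent")
  if (!setequal(ed$child, nonroot))
    return("every non-root node must have exactly one parent")
  if (!all(ed$parent %in% nd$label)) return("edge parent not a node")
  if (nrow(ed) > 0 && any(ed$weight < 0)) return("negative edge weight")
  # reachability from root (no cycles possible given single parents + cover)
  reach <- object@rootLabel
  repeat {
    nxt <- ed$child[ed$parent %in% reach & !(ed$child %in% reach)]
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  if (!setequal(reach, nd$label)) return("tree is not connected to the root")
  unob <- nd$label[!nd$observed]
  if (length(unob)) {
    if (any(nd$abundance[!nd$observed] != 0L))
      return("unobserved nodes must have abundance 0")
    kids <- table(factor(ed$parent, levels = unob))
    if (any(kids < 2L))
      return("unobserved nodes must have at least 2 children")
  }
  if (length(object@sequences)) {
    if (is.null(names(object@sequences)))
      return("sequences must be named by node label")
    if (!all(names(object@sequences) %in% nd$label))
      return("sequence names must be node labels")
  }
  TRUE
})

#' MetricReport: tree-comparison metric values for one tree pair
#'
#' @slot gedTree exact tree-based graph edit distance (integer).
#' @slot gedPath path-based graph edit distance (integer).
#' @slot gedPathNoUnobserved path-based GED with unobserved nodes removed
#'   from every path before comparison.
#' @slot mrca all-observed-pairs MRCA distance in [0,1].
#' @slot coar leaf-averaged COAR distance in [0,1].
#'
#' @seealso [compareTrees()]
#' @export
setClass("MetricReport",
  representation(
    gedTree = "integer",
    gedPath = "integer",
    gedPathNoUnobserved = "integer",
    mrca = "numeric",
    coar = "numeric"
  )
)

setValidity("MetricReport", function(object) {
  if (object@gedTree < 0L || object@gedPath < 0L ||
      object@gedPathNoUnobserved < 0L)
    return("GED values must be non-negative")
  if (object@mrca < 0 || object@mrca > 1) return("mrca must be in [0,1]")
  if (object@coar < 0 || object@coar > 1) return("coar must be in [0,1]")
  TRUE
})

#' SimulatedLineage: ground-truth tree plus sampled sequence records
#'
#' @slot truth [LineageTree-class] carrying the true sequence of every node;
#'   the \code{observed} flag records which nodes were sampled.
#' @slot records data.frame of observed records with columns \code{id},
#'   \code{seq}, \code{abundance}.
#' @slot seed integer seed that reproduces the lineage.
#' @slot config the [simConfig()] list used.
#'
#' @seealso [simulateLineage()]
#' @export
setClass("SimulatedLineage",
  representation(
    truth = "LineageTree",
    records = "data.frame",
    seed = "integer",
    config = "list"
  )
)

setValidity("SimulatedLineage", function(object) {
  rec <- object@records
  if (!all(c("id", "seq", "abundance") %in% names(rec)))
    return("records must have columns id, seq, abundance")
  sq <- object@truth@sequences
  if (nrow(rec) && !all(rec$seq == unname(sq[rec$id])))
    return("record sequences must equal their truth node sequences")
  TRUE
})
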