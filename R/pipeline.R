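#' Reconstruct ancestral sequences of unobserved nodes
#'
#' Assigns a parsimony sequence to every unobserved node that lacks one:
#' in pre-order (so a node's parent is resolved first), each alignment
#' column takes the symbol its sequence-bearing children agree on, falling
#' back to the parent's symbol on disagreement or when no child has a
#' sequence yet. This is the same rule the tree editor applies when it
#' interposes an inferred ancestor, generalised to any number of children.
#'
#' @param tree a [LineageTree-class] whose observed nodes carry sequences.
#' @return the tree with sequences on every node.
#' @export
reconstructAncestralSequences <- function(tree) {
  sq <- tree@sequences
  obs <- stats::setNames(tree@nodes$observed, tree@nodes$label)
  for (lab in preorderLabels(tree)) {
    if (lab %in% names(sq) && !is.na(sq[[lab]])) next
    par <- parentOf(tree, lab)
    if (is.na(par) || !(par %in% names(sq)))
      stop(sprintf("cannot reconstruct sequence for '%s': no parent sequence",
                   lab), call. = FALSE)
    sp <- charToRaw(sq[[par]])
    kids <- childrenOf(tree, lab)
    kidSeqs <- lapply(kids[kids %in% names(sq)],
                      function(k) charToRaw(sq[[k]]))
    kidSeqs <- Filter(function(x) length(x) == length(sp), kidSeqs)
    out <- sp
    if (length(kidSeqs) >= 2L) {
      m <- do.call(rbind, kidSeqs)
      agree <- apply(m, 2L, function(col) all(col == col[1L]))
      out[agree] <- m[1L, agree]
    } else if (length(kidSeqs) == 1L) {
      # single informative child: keep the parent symbol (ties go up)
    }
    sq[lab] <- rawToChar(out)
  }
  tree@sequences <- sq
  tree
}

#' Run the full lineage reconstruction pipeline
#'
#' Reads sequences, aligns them if needed, collapses genotypes, builds the
#' distance matrix and genotype graph, grows the tree by the
#' abundance-aware minimum spanning tree, and applies the two editing
#' steps. The three switches mirror the method's parameters: the abundance
#' objective, unobserved-ancestor insertion, and depth reduction (all on
#' by default, the best-performing configuration). Output files (newick,
#' edgelist, DOT, JSON summary) are written when \code{outdir} is given;
#' re-running on the same input reproduces them byte for byte.
#'
#' @param fasta input FASTA of clonally related nucleotide sequences
#'   (optionally "id@count" headers).
#' @param rootId record id of the inferred unmutated ancestor.
#' @param outdir optional output directory (created if missing).
#' @param abundanceTable optional sidecar TSV (id TAB count).
#' @param useAbundance secondary abundance objective in the builder
#'   (parameter "a").
#' @param insertNodes insert unobserved internal ancestors
#'   (parameter "r").
#' @param depthReduce apply depth-reducing detach/reattach moves
#'   (parameter "t").
#' @param delta optional graph-sparsification threshold (see
#'   [buildLineageGraph()]).
#' @param alignMode "auto" picks "none" for equal-length input and
#'   "builtin" otherwise; or any mode of [alignSequences()].
#' @param verbose log one line per pipeline stage.
#' @return invisibly, a list with elements \code{tree}
#'   ([LineageTree-class]), \code{table}, \code{matrix}, \code{graph} and
#'   \code{summary} (named list).
#' @export
runBuild <- function(fasta, rootId, outdir = NULL, abundanceTable = NULL,
                     useAbundance = TRUE, insertNodes = TRUE,
                     depthReduce = TRUE, delta = NULL,
                     alignMode = "auto", verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  records <- readFastaAbundance(fasta, abundanceTable)
  say("read: %d records, total abundance %d", nrow(records),
      sum(records$abundance))
  if (alignMode == "auto")
    alignMode <- if (length(unique(nchar(records$seq))) == 1L)
      "none" else "builtin"
  records <- alignSequences(records, mode = alignMode)
  say("align (%s): length %d", alignMode, nchar(records$seq[1L]))
  table <- collapseGenotypes(records, rootId)
  say("collapse: %d genotypes", length(table@label))
  mat <- buildDistanceMatrix(table)
  graph <- buildLineageGraph(mat, abundances(table), rootLabel(table),
                             delta = delta)
  tree <- buildTree(graph, useAbundance = useAbundance)
  tree <- setTreeSequences(tree, stats::setNames(table@seq, table@label))
  say("build: cost %d, depth %d", treeCost(tree), treeDepth(tree))
  if (insertNodes) {
    tree <- insertUnobservedNodes(tree, mat)
    say("insert unobserved: %d nodes", nrow(tree@nodes))
  }
  if (depthReduce) {
    tree <- reduceDepth(tree, mat)
    say("reduce depth: cost %d, depth %d", treeCost(tree), treeDepth(tree))
  }
  summary <- list(
    records = nrow(records),
    genotypes = length(table@label),
    nodes = nrow(tree@nodes),
    unobserved_nodes = sum(!tree@nodes$observed),
    cost = treeCost(tree),
    depth = treeDepth(tree),
    root = rootLabel(tree),
    flags = list(abundance = useAbundance, insert_nodes = insertNodes,
                 depth_reduce = depthReduce),
    delta = if (is.null(delta)) NA else delta,
    align_mode = alignMode)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeLineageTree(tree, "newick", file.path(outdir, "tree.nwk"))
    writeLineageTree(tree, "edgelist", file.path(outdir, "tree.edgelist"))
    writeLineageTree(tree, "dot", file.path(outdir, "tree.dot"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(tree = tree, table = table, matrix = mat, graph = graph,
                 summary = summary))
}

#' Compare two lineage tree files
#'
#' Reads two trees (newick or edgelist as written by
#' [writeLineageTree()]), attaches sequences from a FASTA, reconstructs
#' sequences for unobserved nodes, and reports all metrics: exact
#' tree-based GED, path-based GED (with and without unobserved nodes),
#' MRCA and COAR.
#'
#' @param t1Path,t2Path tree files.
#' @param fasta FASTA whose record ids cover the observed labels of both
#'   trees.
#' @param outPath optional TSV file for the single-row report.
#' @param gedMaxNodes exact-GED size bound (see [gedTree()]).
#' @return a [MetricReport-class], invisibly when written to file.
#' @export
runCompare <- function(t1Path, t2Path, fasta, outPath = NULL,
                       gedMaxNodes = 12L) {
  records <- readFastaAbundance(fasta)
  sq <- stats::setNames(records$seq, records$id)
  readOne <- function(p) {
    tree <- readLineageTree(p)
    miss <- setdiff(tree@nodes$label[tree@nodes$observed], names(sq))
    if (length(miss))
      stop(sprintf("FASTA missing sequence(s) for label(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    tree <- setTreeSequences(tree, sq)
    reconstructAncestralSequences(tree)
  }
  t1 <- readOne(t1Path)
  t2 <- readOne(t2Path)
  report <- compareTrees(t1, t2, gedMaxNodes = gedMaxNodes)
  if (!is.null(outPath)) {
    utils::write.table(asMetricRow(report), outPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' Simulate a lineage and write its files
#'
#' Writes the observed records as a FASTA with "id@abundance" headers, the
#' ground-truth tree as newick and edgelist, and a JSON echo of the
#' configuration. Re-running with the same configuration (seed included)
#' reproduces the files byte for byte.
#'
#' @param config a [simConfig()] list.
#' @param outdir output directory (created if missing).
#' @return invisibly, the [SimulatedLineage-class].
#' @export
runSimulate <- function(config, outdir) {
  sim <- simulateLineage(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeLines(paste0(">", sim@records$id, "@", sim@records$abundance, "\n",
                    sim@records$seq),
             file.path(outdir, "observed.fasta"))
  writeLineageTree(sim@truth, "newick", file.path(outdir, "truth.nwk"))
  writeLineageTree(sim@truth, "edgelist",
                   file.path(outdir, "truth.edgelist"))
  jsonlite::write_json(sim@config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sim)
}
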