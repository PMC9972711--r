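#' Read BCR sequences with abundance annotations
#'
#' Reads a FASTA of clonally related nucleotide sequences. A header may
#' carry its read count as an "id@count" suffix (the common convention in
#' collapsed repertoire FASTA files); unannotated records count 1. An
#' optional sidecar TSV (two columns: id, count, no header) overrides the
#' header counts.
#'
#' @param path FASTA file.
#' @param abundanceTable optional TSV path.
#' @return data.frame with columns \code{id}, \code{seq}, \code{abundance},
#'   in file order. Sequences are upper-cased and restricted to
#'   \{A,C,G,T,N\}.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1@5", "ACGT", ">s2", "ACGA"), fa)
#' readFastaAbundance(fa)
#' @export
readFastaAbundance <- function(path, abundanceTable = NULL) {
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e)
                   stop(sprintf("malformed FASTA '%s': %s", path,
                                conditionMessage(e)), call. = FALSE))
  if (length(ss) == 0L) stop("no records in FASTA file", call. = FALSE)
  headers <- sub("\\s.*$", "", names(ss))  # keep first whitespace token
  has_ab <- grepl("@[0-9]+$", headers)
  ids <- ifelse(has_ab, sub("@[0-9]+$", "", headers), headers)
  ab <- rep(1L, length(ids))
  ab[has_ab] <- as.integer(sub("^.*@", "", headers[has_ab]))
  if (any(ids == ""))
    stop("empty record identifier in FASTA", call. = FALSE)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate record id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop(sprintf("non-ACGTN characters in record(s): %s",
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  if (any(nchar(seqs) == 0L))
    stop(sprintf("empty sequence in record(s): %s",
                 paste(ids[nchar(seqs) == 0L], collapse = ", ")),
         call. = FALSE)
  if (!is.null(abundanceTable)) {
    tab <- utils::read.delim(abundanceTable, header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
      stop("abundance table needs two columns: id TAB count", call. = FALSE)
    unknown <- setdiff(tab[[1L]], ids)
    if (length(unknown))
      stop(sprintf("abundance table id(s) not in FASTA: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    ab[match(tab[[1L]], ids)] <- as.integer(tab[[2L]])
  }
  if (any(is.na(ab) | ab < 1L))
    stop("abundances must be positive integers", call. = FALSE)
  data.frame(id = unname(ids), seq = unname(seqs), abundance = ab,
             stringsAsFactors = FALSE)
}

#' Collapse identical sequences into genotypes
#'
#' Groups records with identical aligned sequences into genotypes; the
#' genotype abundance is the sum of its members' counts, so total abundance
#' is conserved. The genotype keeps the id of its first member in input
#' order; the genotype containing \code{rootId} is designated the root.
#'
#' @param records data.frame as from [readFastaAbundance()] (columns id,
#'   seq, abundance), sequences all the same length (align first if not).
#' @param rootId id of the inferred unmutated ancestor among the records.
#' @return a [GenotypeTable-class].
#' @export
collapseGenotypes <- function(records, rootId) {
  if (!rootId %in% records$id)
    stop(sprintf("root id '%s' not among the records", rootId),
         call. = FALSE)
  L <- unique(nchar(records$seq))
  if (length(L) != 1L)
    stop("sequences have unequal lengths; align them first", call. = FALSE)
  grp <- match(records$seq, unique(records$seq))
  first <- !duplicated(grp)
  label <- records$id[first]
  seq <- records$seq[first]
  ab <- as.integer(tapply(records$abundance, grp, sum))
  rootLabel <- label[grp[match(rootId, records$id)]]
  new("GenotypeTable", label = label, seq = seq, abundance = ab,
      rootLabel = rootLabel, alignmentLength = as.integer(L))
}

.fmt_label <- function(label, abundance) sprintf("%s@%d", label, abundance)

.newick_node <- function(tree, label, ab) {
  kids <- childrenOf(tree, label)
  self <- .fmt_label(label, ab[[label]])
  if (!length(kids)) return(self)
  w <- tree@edges$weight[match(kids, tree@edges$child)]
  inner <- paste(sprintf("%s:%d", vapply(kids, .newick_node, "", tree = tree,
                                         ab = ab), w),
                 collapse = ",")
  paste0("(", inner, ")", self)
}

#' Serialize a lineage tree
#'
#' Three text formats are supported. \code{newick}: branch lengths are the
#' integer edge weights, every label (internal nodes included) carries an
#' "@abundance" suffix, unobserved nodes are recognisable by the "U<k>"
#' label plus "@0". \code{edgelist}: one "parent TAB child TAB weight TAB
#' child_abundance" row per edge (a header row "#root TAB <label> TAB <ab>"
#' carries the root). \code{dot}: Graphviz with abundance-annotated nodes.
#' \code{newick} and \code{edgelist} round-trip through [readLineageTree()].
#'
#' @param tree a [LineageTree-class].
#' @param format one of "newick", "edgelist", "dot".
#' @param path optional file to write; the text is returned invisibly then.
#' @return the serialized text (a character scalar).
#' @export
writeLineageTree <- function(tree, format = c("newick", "edgelist", "dot"),
                             path = NULL) {
  format <- match.arg(format)
  ab <- abundances(tree)
  txt <- switch(format,
    newick = {
      root <- tree@rootLabel
      kids <- childrenOf(tree, root)
      if (!length(kids)) {
        paste0(.fmt_label(root, ab[[root]]), ";")
      } else paste0(.newick_node(tree, root, ab), ";")
    },
    edgelist = {
      hdr <- sprintf("#root\t%s\t%d", tree@rootLabel, ab[[tree@rootLabel]])
      if (nrow(tree@edges)) {
        rows <- sprintf("%s\t%s\t%d\t%d", tree@edges$parent,
                        tree@edges$child, tree@edges$weight,
                        ab[tree@edges$child])
        paste(c(hdr, rows), collapse = "\n")
      } else hdr
    },
    dot = {
      nd <- tree@nodes
      decl <- sprintf(
        "  \"%s\" [label=\"%s\\n%d\", shape=%s, width=%.2f];",
        nd$label, nd$label, nd$abundance,
        ifelse(nd$observed, "circle", "box"),
        0.5 + 0.15 * log1p(nd$abundance))
      edg <- if (nrow(tree@edges))
        sprintf("  \"%s\" -> \"%s\" [label=\"%d\"];", tree@edges$parent,
                tree@edges$child, tree@edges$weight) else character(0)
      paste(c("digraph lineage {", decl, edg, "}"), collapse = "\n")
    })
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

.parse_label <- function(raw) {
  has <- grepl("@[0-9]+$", raw)
  if (!all(has))
    stop(sprintf("label(s) missing '@abundance' suffix: %s",
                 paste(raw[!has], collapse = ", ")), call. = FALSE)
  list(label = sub("@[0-9]+$", "", raw),
       abundance = as.integer(sub("^.*@", "", raw)))
}

#' Read a lineage tree
#'
#' Reads the newick or edgelist dialect written by [writeLineageTree()].
#' The format is detected from the content (a leading "(" or a single
#' "label@abundance;" means newick). Nodes labelled "U<k>" with abundance 0
#' are flagged unobserved.
#'
#' @param path tree file.
#' @param sequenceMap optional named character vector label -> sequence;
#'   attached to the tree (required downstream by the MRCA/COAR metrics).
#' @return a [LineageTree-class].
#' @export
readLineageTree <- function(path, sequenceMap = NULL) {
  lines <- readLines(path, warn = FALSE)
  body <- trimws(paste(lines, collapse = "\n"))
  tree <- if (grepl("^\\(", body) || grepl("^[^\t\n]+;$", body)) {
    .read_newick(body)
  } else {
    .read_edgelist(lines)
  }
  if (!is.null(sequenceMap)) {
    need <- setdiff(tree@nodes$label[tree@nodes$observed],
                    names(sequenceMap))
    if (length(need))
      stop(sprintf("sequence map missing label(s): %s",
                   paste(need, collapse = ", ")), call. = FALSE)
    tree <- setTreeSequences(tree, sequenceMap)
  }
  tree
}

.read_newick <- function(text) {
  if (!grepl("\\(", text)) {           # single-node tree
    lab <- .parse_label(sub(";$", "", trimws(text)))
    return(LineageTree(
      edges = data.frame(parent = character(), child = character(),
                         weight = integer()),
      rootLabel = lab$label,
      abundance = stats::setNames(lab$abundance, lab$label),
      autoUnobserved = TRUE))
  }
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse newick", call. = FALSE)
  raw <- c(phy$tip.label, phy$node.label)
  lab <- .parse_label(raw)
  parent <- lab$label[phy$edge[, 1L]]
  child <- lab$label[phy$edge[, 2L]]
  w <- as.integer(round(phy$edge.length))
  rootIdx <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  LineageTree(
    edges = data.frame(parent = parent, child = child, weight = w),
    rootLabel = lab$label[rootIdx],
    abundance = stats::setNames(lab$abundance, lab$label),
    autoUnobserved = TRUE)
}

.read_edgelist <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^#root\t", lines)
  if (!any(hdr)) stop("edgelist missing '#root' header row", call. = FALSE)
  rootParts <- strsplit(lines[hdr][1L], "\t", fixed = TRUE)[[1L]]
  rootLabel <- rootParts[2L]
  rootAb <- as.integer(rootParts[3L])
  rows <- lines[!hdr]
  if (!length(rows)) {
    return(LineageTree(
      edges = data.frame(parent = character(), child = character(),
                         weight = integer()),
      rootLabel = rootLabel,
      abundance = stats::setNames(rootAb, rootLabel),
      autoUnobserved = TRUE))
  }
  parts <- strsplit(rows, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("edgelist rows must be: parent TAB child TAB weight TAB abundance",
         call. = FALSE)
  m <- do.call(rbind, parts)
  child <- m[, 2L]
  if (anyDuplicated(child))
    stop(sprintf("node(s) with more than one parent in edgelist: %s",
                 paste(unique(child[duplicated(child)]), collapse = ", ")),
         call. = FALSE)
  ab <- stats::setNames(as.integer(m[, 4L]), child)
  ab[rootLabel] <- rootAb
  LineageTree(
    edges = data.frame(parent = m[, 1L], child = child,
                       weight = as.integer(m[, 3L])),
    rootLabel = rootLabel, abundance = ab, autoUnobserved = TRUE)
}
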