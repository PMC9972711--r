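#' DistanceMatrix: pairwise genotype distances
#'
#' Raw (integer mismatch count) and normalised (raw / alignment length)
#' hamming distances between all genotype pairs of one lineage.
#'
#' @slot label ordered genotype labels.
#' @slot raw symmetric integer matrix of mismatch counts.
#' @slot normalised symmetric numeric matrix in [0,1].
#' @slot alignmentLength the shared alignment length.
#'
#' @seealso [buildDistanceMatrix()]
#' @export
setClass("DistanceMatrix",
  representation(label = "character", raw = "matrix",
                 normalised = "matrix", alignmentLength = "integer"))

setValidity("DistanceMatrix", function(object) {
  n <- length(object@label)
  if (!all(dim(object@raw) == c(n, n)) ||
      !all(dim(object@normalised) == c(n, n)))
    return("matrix dimensions must match the number of labels")
  if (any(diag(object@raw) != 0)) return("diagonal must be zero")
  if (!isTRUE(all.equal(object@raw, t(object@raw))))
    return("raw matrix must be symmetric")
  if (!isTRUE(all.equal(object@normalised,
                        object@raw / object@alignmentLength)))
    return("normalised must equal raw / alignmentLength")
  TRUE
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix: %d genotypes, alignment length %d\n",
              length(object@label), object@alignmentLength))
})

#' Hamming distance between two aligned sequences
#'
#' Counts mismatching alignment columns. A gap against a base is one
#' mismatch (one indel event = one difference); a gap against a gap is a
#' match. 'N' is an ambiguity placeholder and mismatches every symbol,
#' including another 'N'.
#'
#' @param a,b equal-length character scalars over \{A,C,G,T,N,-\}.
#' @return non-negative integer.
#' @examples
#' hammingDistance("ACGT", "ACGA")  # 1
#' hammingDistance("AC-T", "ACGT")  # 1
#' @export
hammingDistance <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb))
    stop(sprintf("sequences differ in length (%d vs %d)",
                 length(ra), length(rb)), call. = FALSE)
  N <- as.raw(78L)  # 'N'
  sum(ra != rb | (ra == N & rb == N))
}

.degap <- function(x) gsub("-", "", x, fixed = TRUE)

# Center-star progressive alignment on pairwise Needleman-Wunsch
# (match 0, mismatch -1, gap -2 per position, linear gap cost).
.nw_sub_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- c("A", "C", "G", "T", "N")
      mm <- matrix(-1, 5, 5, dimnames = list(letters, letters))
      diag(mm) <- 0
      mm["N", "N"] <- -1  # N never matches, not even itself
      m <<- mm
    }
    m
  }
})

.nw_pair <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b), type = "global",
    substitutionMatrix = .nw_sub_matrix(),
    gapOpening = 0, gapExtension = 2)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

# Merge two gapped copies of the same center string into a common gap
# pattern; returns index maps from merged columns to columns of each copy
# (NA where the copy needs a new gap).
.merge_center <- function(c1, c2) {
  x1 <- strsplit(c1, "")[[1L]]
  x2 <- strsplit(c2, "")[[1L]]
  i <- 1L; j <- 1L
  map1 <- integer(0); map2 <- integer(0)
  while (i <= length(x1) || j <= length(x2)) {
    g1 <- i <= length(x1) && x1[i] == "-"
    g2 <- j <= length(x2) && x2[j] == "-"
    if (i <= length(x1) && j <= length(x2) && !g1 && !g2) {
      map1 <- c(map1, i); map2 <- c(map2, j); i <- i + 1L; j <- j + 1L
    } else if (g1) {
      map1 <- c(map1, i); map2 <- c(map2, NA); i <- i + 1L
    } else {
      map1 <- c(map1, NA); map2 <- c(map2, j); j <- j + 1L
    }
  }
  list(map1 = map1, map2 = map2)
}

.apply_map <- function(seq, map) {
  x <- strsplit(seq, "")[[1L]]
  out <- rep("-", length(map))
  out[!is.na(map)] <- x[map[!is.na(map)]]
  paste(out, collapse = "")
}

.center_star <- function(seqs) {
  k <- length(seqs)
  if (k == 1L) return(seqs)
  # center = sequence maximising total pairwise NW score (most central);
  # ties broken by input order
  scores <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    s <- .nw_pair(seqs[i], seqs[j])$score
    scores[i, j] <- s; scores[j, i] <- s
  }
  center <- which.max(rowSums(scores))
  masterCenter <- seqs[center]           # gapped copy of the center
  aligned <- seqs
  aligned[center] <- masterCenter
  done <- center
  for (i in setdiff(seq_len(k), center)) {
    pw <- .nw_pair(seqs[center], seqs[i])
    mg <- .merge_center(masterCenter, pw$a)
    masterCenter <- .apply_map(masterCenter, mg$map1)
    for (d in done) aligned[d] <- .apply_map(aligned[d], mg$map1)
    aligned[i] <- .apply_map(pw$b, mg$map2)
    done <- c(done, i)
  }
  aligned
}

#' Align clonally related sequences
#'
#' Produces equal-length sequences for distance computation. Mode
#' \code{none} asserts the inputs are already aligned (the usual case for
#' collapsed clonal data without indels); \code{builtin} runs a
#' deterministic center-star progressive alignment on pairwise global
#' Needleman-Wunsch (match 0, mismatch -1, gap -2), adequate for the
#' near-identical sequences of one clonal lineage; \code{external} shells
#' out to a multiple-sequence-alignment binary (default \code{mafft}).
#' Removing the gaps of any output sequence restores its input.
#'
#' @param records data.frame with columns id, seq, abundance.
#' @param mode one of "none", "builtin", "external".
#' @param binary external aligner program (mode "external").
#' @return the records with aligned (possibly gapped) \code{seq}.
#' @export
alignSequences <- function(records, mode = c("none", "builtin", "external"),
                           binary = "mafft") {
  mode <- match.arg(mode)
  if (mode == "none") {
    if (length(unique(nchar(records$seq))) > 1L)
      stop("mode 'none' requires equal-length sequences; choose 'builtin' ",
           "or 'external'", call. = FALSE)
    return(records)
  }
  if (mode == "builtin") {
    records$seq <- .center_star(records$seq)
    return(records)
  }
  exe <- Sys.which(binary)
  if (!nzchar(exe))
    stop(sprintf(
      "external aligner '%s' not found on PATH; install it or use mode 'builtin'",
      binary), call. = FALSE)
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(">", records$id, "\n", records$seq), fin)
  status <- system2(exe, c("--auto", "--quiet", "--preservecase", fin),
                    stdout = fout)
  if (status != 0L)
    stop(sprintf("aligner '%s' exited with status %d", binary, status),
         call. = FALSE)
  ss <- Biostrings::readBStringSet(fout)
  out <- toupper(as.character(ss))
  records$seq <- unname(out[match(records$id, names(ss))])
  records
}

#' Pairwise distance matrix of a genotype table
#'
#' Computes the raw hamming mismatch count and its normalisation by the
#' alignment length for every genotype pair; the raw counts weight the
#' lineage graph edges, the normalised values feed the MRCA metric.
#'
#' @param table a [GenotypeTable-class].
#' @return a [DistanceMatrix-class].
#' @export
buildDistanceMatrix <- function(table) {
  n <- length(table@label)
  raw <- matrix(0L, n, n, dimnames = list(table@label, table@label))
  rawseqs <- lapply(table@seq, charToRaw)
  N <- as.raw(78L)
  if (n > 1L) for (i in seq_len(n - 1L)) {
    ri <- rawseqs[[i]]
    for (j in seq.int(i + 1L, n)) {
      rj <- rawseqs[[j]]
      d <- sum(ri != rj | (ri == N & rj == N))
      raw[i, j] <- d
      raw[j, i] <- d
    }
  }
  new("DistanceMatrix", label = table@label, raw = raw,
      normalised = raw / table@alignmentLength,
      alignmentLength = table@alignmentLength)
}

#' Export a distance matrix as TSV text
#' @param matrix a [DistanceMatrix-class].
#' @param path optional file to write.
#' @param normalised write the normalised rather than raw distances.
#' @return the TSV text, invisibly when written to file.
#' @export
writeDistanceMatrix <- function(matrix, path = NULL, normalised = FALSE) {
  m <- if (normalised) matrix@normalised else matrix@raw
  hdr <- paste(c("", matrix@label), collapse = "\t")
  rows <- vapply(seq_along(matrix@label), function(i)
    paste(c(matrix@label[i], m[i, ]), collapse = "\t"), "")
  txt <- paste(c(hdr, rows), collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

.components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    frontier <- s
    comp[s] <- k
    while (length(frontier)) {
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & is.na(comp))
      comp[nxt] <- k
      frontier <- nxt
    }
  }
  comp
}

#' Build the weighted genotype graph
#'
#' Assembles the undirected graph the spanning-tree builder consumes: all
#' genotype pairs connected with their raw hamming distance as edge weight.
#' A threshold \code{delta} sparsifies the graph by removing edges whose
#' weight exceeds \code{delta} (long edges carry no lineage signal); the
#' literal complementary rule (remove edges with weight strictly below
#' \code{delta}) is available via \code{deltaBelow = TRUE} for
#' compatibility. Pruning that disconnects the graph is an error naming
#' the components and the smallest delta that keeps it connected.
#'
#' @param matrix a [DistanceMatrix-class].
#' @param abundance named integer vector of genotype abundances.
#' @param rootLabel label of the root genotype.
#' @param delta optional non-negative threshold.
#' @param deltaBelow use the literal "remove edges below delta" rule.
#' @return a [LineageGraph-class].
#' @export
buildLineageGraph <- function(matrix, abundance, rootLabel, delta = NULL,
                              deltaBelow = FALSE) {
  labels <- matrix@label
  if (!rootLabel %in% labels)
    stop(sprintf("root label '%s' not in distance matrix", rootLabel),
         call. = FALSE)
  if (!all(labels %in% names(abundance)))
    stop("abundance vector must cover all genotype labels", call. = FALSE)
  w <- matrix@raw
  storage.mode(w) <- "integer"
  if (!is.null(delta)) {
    if (delta < 0) stop("delta must be >= 0", call. = FALSE)
    off <- row(w) != col(w)
    drop <- if (deltaBelow) off & w < delta else off & w > delta
    w[drop] <- NA_integer_
    adj <- !is.na(w) & off
    comp <- .components(adj)
    if (length(unique(comp)) > 1L) {
      sizes <- split(labels, comp)
      minDelta <- if (deltaBelow) NA_real_ else {
        cand <- sort(unique(matrix@raw[row(matrix@raw) != col(matrix@raw)]))
        cand[which(vapply(cand, function(d) {
          a <- matrix@raw <= d & row(w) != col(w)
          length(unique(.components(a))) == 1L
        }, logical(1)))[1L]]
      }
      stop(sprintf(
        "delta = %g disconnects the genotype graph into %d components (%s)%s",
        delta, length(sizes),
        paste(vapply(sizes, function(s) paste(s, collapse = ","), ""),
              collapse = " | "),
        if (!is.na(minDelta))
          sprintf("; smallest connecting delta is %g", minDelta) else ""),
        call. = FALSE)
    }
  }
  new("LineageGraph", label = labels, weight = w,
      abundance = as.integer(abundance[labels]), rootLabel = rootLabel,
      delta = if (is.null(delta)) numeric(0) else as.numeric(delta))
}
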