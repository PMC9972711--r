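# Independent oracles and fixture generators. Everything here is written
# from first principles (enumeration, brute force, or a third-party
# library) and never calls the package's production code paths it checks.

# --- fixtures -------------------------------------------------------------

random_sequence <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# random rooted tree as a LineageTree: node i's parent drawn among 1..i-1
random_tree <- function(n, maxWeight = 5L, labels = NULL, seqLen = NULL) {
  if (is.null(labels)) labels <- sprintf("n%d", seq_len(n))
  if (n == 1L) {
    tr <- LineageTree(data.frame(parent = character(), child = character(),
                                 weight = integer()), labels[1L])
  } else {
    parent <- labels[vapply(2:n, function(i) sample.int(i - 1L, 1L),
                            integer(1))]
    tr <- LineageTree(data.frame(parent = parent, child = labels[2:n],
                                 weight = sample.int(maxWeight, n - 1L,
                                                     replace = TRUE)),
                      labels[1L])
  }
  if (!is.null(seqLen)) {
    sq <- stats::setNames(vapply(seq_len(n), function(i)
      random_sequence(seqLen), ""), labels)
    tr <- setTreeSequences(tr, sq)
  }
  tr
}

# random connected undirected weighted graph as a LineageGraph;
# m extra edges on top of a random spanning tree
random_graph <- function(n, extraEdges = 2L, maxWeight = 6L) {
  labels <- sprintf("g%d", seq_len(n))
  w <- matrix(NA_integer_, n, n, dimnames = list(labels, labels))
  diag(w) <- 0L
  for (i in 2:n) {
    j <- sample.int(i - 1L, 1L)
    w[i, j] <- w[j, i] <- sample.int(maxWeight, 1L)
  }
  free <- which(upper.tri(w) & is.na(w))
  if (length(free) && extraEdges > 0L) {
    pick <- free[sample.int(length(free), min(extraEdges, length(free)))]
    w[pick] <- sample.int(maxWeight, length(pick), replace = TRUE)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
  }
  new("LineageGraph", label = labels, weight = w,
      abundance = sample.int(9L, n, replace = TRUE), rootLabel = labels[1L],
      delta = numeric(0))
}

# --- brute-force minimum spanning tree cost ------------------------------

# enumerate all (n-1)-edge subsets, keep spanning trees, minimise weight
bruteforce_mst_cost <- function(graph) {
  w <- graph@weight
  n <- nrow(w)
  idx <- which(upper.tri(w) & !is.na(w), arr.ind = TRUE)
  m <- nrow(idx)
  if (m < n - 1L) return(NA_integer_)
  best <- Inf
  for (sel in utils::combn(m, n - 1L, simplify = FALSE)) {
    e <- idx[sel, , drop = FALSE]
    # connectivity check by label propagation
    comp <- seq_len(n)
    for (k in seq_len(nrow(e))) {
      a <- comp[e[k, 1L]]; b <- comp[e[k, 2L]]
      comp[comp == b] <- a
    }
    if (length(unique(comp)) != 1L) next
    cost <- sum(w[e])
    if (cost < best) best <- cost
  }
  as.integer(best)
}

igraph_mst_cost <- function(graph) {
  w <- graph@weight
  w[is.na(w)] <- 0L
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  sum(igraph::E(igraph::mst(g))$weight)
}

# --- exhaustive graph edit distance --------------------------------------

# identity of a node for cross-tree matching (mirrors the documented
# contract: observed by label, unobserved by sequence, else unique)
oracle_identity <- function(tree, tag) {
  nd <- tree@nodes
  sq <- tree@sequences
  sapply(seq_len(nrow(nd)), function(i) {
    if (nd$observed[i]) paste0("L", nd$label[i])
    else if (nd$label[i] %in% names(sq)) paste0("S", sq[[nd$label[i]]])
    else paste0("X", tag, nd$label[i])
  })
}

# enumerate every injective partial mapping V1 -> V2 and take the cheapest
# edit script cost; no pruning, usable up to ~6 nodes
exhaustive_ged <- function(t1, t2) {
  id1 <- oracle_identity(t1, "1")
  id2 <- oracle_identity(t2, "2")
  l1 <- t1@nodes$label
  l2 <- t2@nodes$label
  n1 <- length(l1); n2 <- length(l2)
  e1 <- cbind(match(t1@edges$parent, l1), match(t1@edges$child, l1))
  e2 <- cbind(match(t2@edges$parent, l2), match(t2@edges$child, l2))
  e2key <- paste(e2[, 1L], e2[, 2L])
  best <- Inf
  assign <- integer(n1)
  recurse <- function(k) {
    if (k > n1) {
      cost <- sum(vapply(seq_len(n1), function(i) {
        if (assign[i] == 0L) 1L
        else if (id1[i] == id2[assign[i]]) 0L else 1L
      }, integer(1)))
      cost <- cost + sum(!(seq_len(n2) %in% assign))
      matched <- character(0)
      for (r in seq_len(nrow(e1))) {
        fa <- assign[e1[r, 1L]]; fb <- assign[e1[r, 2L]]
        key <- paste(fa, fb)
        if (fa > 0L && fb > 0L && key %in% e2key) matched <- c(matched, key)
        else cost <- cost + 1L
      }
      cost <- cost + (nrow(e2) - length(matched))
      if (cost < best) best <<- cost
      return(invisible())
    }
    for (v in c(setdiff(seq_len(n2), assign[seq_len(k - 1L)]), 0L)) {
      assign[k] <<- v
      recurse(k + 1L)
      assign[k] <<- 0L
    }
  }
  recurse(1L)
  as.integer(best)
}

# --- token Levenshtein oracle via utils::adist ---------------------------

adist_levenshtein <- function(a, b) {
  tokens <- unique(c(a, b))
  stopifnot(length(tokens) <= length(letters))
  enc <- function(x) paste(letters[match(x, tokens)], collapse = "")
  as.integer(utils::adist(enc(a), enc(b)))
}

# --- small constructors ---------------------------------------------------

# tree from "parent child weight" strings, e.g. edges("r a 1", "a b 2")
make_tree <- function(..., root, abundance = NULL, observed = NULL,
                      sequences = NULL) {
  rows <- if (...length()) strsplit(c(...), "\\s+") else list()
  ed <- if (length(rows))
    data.frame(parent = vapply(rows, `[`, "", 1L),
               child = vapply(rows, `[`, "", 2L),
               weight = as.integer(vapply(rows, `[`, "", 3L)))
  else data.frame(parent = character(), child = character(),
                  weight = integer())
  LineageTree(ed, root, abundance = abundance, observed = observed,
              sequences = sequences)
}

# complete LineageGraph from an explicit symmetric weight matrix
make_graph <- function(weights, abundance, root) {
  labels <- rownames(weights)
  storage.mode(weights) <- "integer"
  new("LineageGraph", label = labels, weight = weights,
      abundance = as.integer(abundance), rootLabel = root,
      delta = numeric(0))
}

write_fasta <- function(records, path) {
  writeLines(paste0(">", records$id,
                    ifelse(is.na(records$abundance), "",
                           paste0("@", records$abundance)),
                    "\n", records$seq), path)
  path
}
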