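#' Simulation configuration for synthetic B-cell lineages
#'
#' Parameters of the branching-process somatic-hypermutation simulator.
#' Defaults emulate germinal-centre lineages of moderate size: a 350 nt
#' rearranged V(D)J-like root, mean 1.5 offspring per cell generation over
#' at most 7 generations (trees of a few to ~100 genotypes, depths mostly
#' 2-7), 2 point mutations per cell division on average, 80% of genotypes
#' sampled with geometric copy numbers around 2.5.
#'
#' @param rootLength root (naive ancestor) sequence length in nt.
#' @param offspringMean Poisson mean number of children per node.
#' @param mutationsPerEdgeMean Poisson mean of point mutations per
#'   parent-to-child edge.
#' @param maxGenerations maximum tree depth in generations.
#' @param observationRate probability that a node is sampled.
#' @param abundanceMean mean sampled copy number (shifted geometric, >= 1).
#' @param hotspotMotifs character vector of 3-mers whose centre position
#'   mutates preferentially (classic SHM WRC/GYW-style motifs by default).
#' @param hotspotMultiplier weight multiplier for hotspot positions
#'   (1 = no bias, the default: the reconstruction itself is
#'   hotspot-agnostic).
#' @param forceRootObserved always include the root among the sampled
#'   records (the usual situation: the unmutated ancestor is supplied).
#' @param uniqueSiteMutations place every mutation at a site never mutated
#'   before anywhere in the lineage, and force >= 1 mutation per edge;
#'   makes all genotypes distinct and pairwise distances additive along
#'   the tree, so the true tree is the unique minimum spanning tree. Set
#'   by [easyRegime()].
#' @param seed integer seed making the lineage reproducible.
#' @return a validated configuration list of class "simConfig".
#' @export
simConfig <- function(rootLength = 350L, offspringMean = 1.5,
                      mutationsPerEdgeMean = 2, maxGenerations = 7L,
                      observationRate = 0.8, abundanceMean = 2.5,
                      hotspotMotifs = c("AGC", "AAC", "GCT", "GTT"),
                      hotspotMultiplier = 1,
                      forceRootObserved = TRUE,
                      uniqueSiteMutations = FALSE,
                      seed = 1L) {
  cfg <- list(rootLength = as.integer(rootLength),
              offspringMean = offspringMean,
              mutationsPerEdgeMean = mutationsPerEdgeMean,
              maxGenerations = as.integer(maxGenerations),
              observationRate = observationRate,
              abundanceMean = abundanceMean,
              hotspotMotifs = hotspotMotifs,
              hotspotMultiplier = hotspotMultiplier,
              forceRootObserved = isTRUE(forceRootObserved),
              uniqueSiteMutations = isTRUE(uniqueSiteMutations),
              seed = as.integer(seed))
  if (cfg$rootLength < 1L) stop("rootLength must be positive")
  if (cfg$offspringMean <= 0) stop("offspringMean must be > 0")
  if (cfg$mutationsPerEdgeMean < 0)
    stop("mutationsPerEdgeMean must be >= 0")
  if (cfg$maxGenerations < 1L) stop("maxGenerations must be positive")
  if (cfg$observationRate < 0 || cfg$observationRate > 1)
    stop("observationRate must be in [0,1]")
  if (cfg$abundanceMean < 1) stop("abundanceMean must be >= 1")
  if (cfg$hotspotMultiplier <= 0) stop("hotspotMultiplier must be > 0")
  class(cfg) <- c("simConfig", "list")
  cfg
}

#' Easy-regime variant of a configuration
#'
#' Returns the configuration adjusted so the simulated lineage is fully
#' identifiable: every node is observed, and every edge carries at least
#' one mutation placed at a previously unmutated site, which makes all
#' genotype sequences distinct, edge weights equal to mutation counts, and
#' the true tree the unique minimum spanning tree of the genotype graph.
#' Used for parameter-recovery validation of the whole pipeline.
#'
#' @param config a [simConfig()] list.
#' @return the adjusted configuration.
#' @export
easyRegime <- function(config) {
  config$observationRate <- 1
  config$forceRootObserved <- TRUE
  config$uniqueSiteMutations <- TRUE
  config
}

.hotspot_weights <- function(seq, motifs, mult) {
  L <- nchar(seq)
  w <- rep(1, L)
  if (mult == 1 || !length(motifs)) return(w)
  for (m in motifs) {
    hits <- gregexpr(m, seq, fixed = TRUE)[[1L]]
    hits <- hits[hits > 0L]
    w[hits + 1L] <- w[hits + 1L] * mult  # centre of the 3-mer
  }
  w
}

.mutate_seq <- function(seq, k, weights, forbidden) {
  if (k == 0L) return(list(seq = seq, sites = integer(0)))
  x <- strsplit(seq, "")[[1L]]
  ok <- setdiff(seq_along(x), forbidden)
  if (length(ok) < k)
    stop("rootLength too small for the requested unique-site mutations; ",
         "increase rootLength or shrink the tree", call. = FALSE)
  sites <- if (length(ok) == 1L) ok else
    sample(ok, k, prob = weights[ok])
  bases <- c("A", "C", "G", "T")
  for (s in sites) x[s] <- sample(setdiff(bases, x[s]), 1L)
  list(seq = paste(x, collapse = ""), sites = sites)
}

#' Simulate a B-cell lineage with known ground truth
#'
#' Grows a lineage by a branching process: the root sequence is uniform
#' over \{A,C,G,T\}^rootLength; each node in generation g produces a
#' Poisson number of children (the root is forced to have at least one, so
#' a lineage always exists) up to \code{maxGenerations}; each child copies
#' its parent with a Poisson number of point substitutions at
#' (optionally hotspot-weighted) positions, always to a different base.
#' Genotypes are then sampled at \code{observationRate} with geometric
#' copy numbers. The returned object carries the full true tree (every
#' node with its true sequence, edge weights equal to parent-child
#' hamming distances) and the observed records ready for the
#' reconstruction pipeline. Fully reproducible from the seed.
#'
#' @param config a [simConfig()] list.
#' @return a [SimulatedLineage-class].
#' @export
simulateLineage <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  rootSeq <- paste(sample(bases, config$rootLength, replace = TRUE),
                   collapse = "")
  labels <- "root"
  seqs <- c(root = rootSeq)
  parents <- c(root = NA_character_)
  gen <- c(root = 0L)
  usedSites <- integer(0)
  frontier <- "root"
  idx <- 1L
  for (g in seq_len(config$maxGenerations)) {
    nextFrontier <- character(0)
    for (node in frontier) {
      k <- stats::rpois(1L, config$offspringMean)
      if (node == "root" && g == 1L) k <- max(k, 1L)
      if (k == 0L) next
      w <- .hotspot_weights(seqs[[node]], config$hotspotMotifs,
                            config$hotspotMultiplier)
      for (ch in seq_len(k)) {
        idx <- idx + 1L
        lab <- sprintf("s%d", idx)
        nm <- stats::rpois(1L, config$mutationsPerEdgeMean)
        if (config$uniqueSiteMutations) nm <- max(nm, 1L)
        forbidden <- if (config$uniqueSiteMutations) usedSites else integer(0)
        mut <- .mutate_seq(seqs[[node]], nm, w, forbidden)
        usedSites <- c(usedSites, mut$sites)
        labels <- c(labels, lab)
        seqs[lab] <- mut$seq
        parents[lab] <- node
        gen[lab] <- g
        nextFrontier <- c(nextFrontier, lab)
      }
    }
    frontier <- nextFrontier
    if (!length(frontier)) break
  }
  sampled <- stats::runif(length(labels)) < config$observationRate
  names(sampled) <- labels
  if (config$forceRootObserved) sampled["root"] <- TRUE
  ab <- stats::setNames(rep(0L, length(labels)), labels)
  nSamp <- sum(sampled)
  if (nSamp)
    ab[sampled] <- stats::rgeom(nSamp, prob = 1 / config$abundanceMean) + 1L
  nonroot <- labels[-1L]
  edges <- data.frame(
    parent = unname(parents[nonroot]),
    child = nonroot,
    weight = vapply(nonroot, function(l)
      hammingDistance(seqs[[parents[[l]]]], seqs[[l]]), integer(1)),
    stringsAsFactors = FALSE)
  truth <- LineageTree(edges = edges, rootLabel = "root",
                       abundance = ab,
                       observed = stats::setNames(rep(TRUE, length(labels)),
                                                  labels),
                       sequences = seqs)
  records <- data.frame(id = labels[sampled],
                        seq = unname(seqs[sampled]),
                        abundance = unname(ab[sampled]),
                        stringsAsFactors = FALSE)
  new("SimulatedLineage", truth = truth, records = records,
      seed = config$seed, config = unclass(config))
}
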