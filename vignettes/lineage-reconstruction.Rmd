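---
title: "Reconstructing B-cell lineage trees with abundance-aware minimum spanning trees"
author: "clonalmst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing B-cell lineage trees with abundance-aware minimum spanning trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalmst)
```

## The model

A B-cell clonal lineage starts from one naive B cell whose rearranged
V(D)J heavy-chain sequence — the *root* — accumulates point mutations
through somatic hypermutation while the clone expands. Sequencing such a
clone yields reads that collapse into *genotypes* (classes of identical
sequences); the number of reads per genotype, its *abundance*, reflects
clonal expansion. The lineage tree is a rooted directed tree over these
genotypes. Three features distinguish it from a species phylogeny and
motivate a purpose-built method: the root is known (the inferred
unmutated ancestor is an input), observed genotypes can be internal
nodes, and multifurcations are routine.

`clonalmst` casts reconstruction as a minimum spanning tree (MST)
problem. Genotypes form a complete undirected graph whose edge weights
are raw hamming distances on a shared multiple sequence alignment; the
reconstruction is a spanning arborescence grown from the root with a
hierarchical bi-objective rule: minimise edge weight first, and among
equal-weight candidates prefer high genotype abundance. Minimising total
edge weight is maximum parsimony — the tree implying the fewest
mutations — and the abundance preference encodes the biological prior
that an expanded genotype is the more plausible progenitor of a variant
equidistant from several possible parents.

### Assumptions

- All input sequences belong to one clone (same V(D)J rearrangement);
  clonal partitioning and germline inference happen upstream.
- Distances are position-uniform hamming counts: mutational hot and cold
  spots are not weighted (a known limitation of the distance model), and
  indels, once aligned, count one difference per gapped column.
- Abundances are meaningful relative quantities (e.g. deduplicated read
  counts), not artefacts of amplification bias.

## The algorithm, step by step

**Genotype collapsing.** Identical aligned sequences merge into one
genotype whose abundance is the sum of its members'; the genotype keeps
the id of its first member in input order, so results are deterministic
for a fixed input file. Total abundance is conserved.

**Distances.** Raw integer mismatch counts weight the graph; the
normalised variant (raw / alignment length) is used only inside the MRCA
metric. Keeping edge weights on the mutation-count scale matters because
the editing update's floor term "1" is only meaningful there; weights in
[0, 1] would make the floor saturate everything. `N` is treated as a
fifth symbol that mismatches everything, including another `N`: a
conservative, deterministic choice for ambiguous base calls. A gap
against a base is one difference (one indel event); gap against gap is a
match (shared absence carries no signal).

**Graph sparsification (optional).** A threshold delta removes edges with
weight *greater* than delta. The complementary reading — removing the
short edges — would delete exactly the informative edges and contradicts
the stated purpose of avoiding a dense graph, so we treat it as an
erratum of the method's original description; it remains available
behind `deltaBelow = TRUE` for compatibility. There is no default delta:
the complete graph is used unless the caller asks otherwise, and pruning
that disconnects the graph is an error that reports the smallest
connecting threshold rather than silently reconnecting.

**Tree growth.** A modified Prim's algorithm: at each step the candidate
(tree node u, outside node v) minimising weight w(u, v) is attached, with
ties broken by (1) larger abundance of v, (2) larger abundance of u, and
(3) lexicographic (u, v) order. The attach-side tie-break (2) is needed
because two equal-weight candidate edges can propose the *same* outside
node from different tree nodes — the abundance of v cannot separate
them — and the method's rule is to attach under the more abundant
parent. Tie-break (3) exists purely for determinism; the underlying
method is silent there.

The default implementation re-examines every tree-to-outside edge at
each step (equivalently, a lazy priority queue with stale-entry
skipping), which provably attains the MST cost. A strict
insert-each-node-once queue — each node enters the queue at its first
discovery and its entry is never improved — is available via
`singleInsertion = TRUE`; it can miss cheaper attachments discovered
later (the test suite contains a 4-node example where it pays one extra
mutation), which is why it is a compatibility flag rather than the
default: the primary objective is stated as minimising the total weight,
and only the lazy variant guarantees that.

**Unobserved-ancestor insertion.** Sampling misses genotypes; when the
distance between sister nodes m, n under parent p satisfies
d_mn &le; min(d_pm, d_pn), the sisters are at least as close to each
other as to their parent and a common ancestor i is interposed with

d_pi = max(d_pm − d_mn, d_pn − d_mn, 1), d_im = d_pm − d_pi,
d_in = d_pn − d_pi.

Design choices here, where the method's description leaves room:

- *Which parent edge triggers?* We use min(d_pm, d_pn) — the strictest
  reading — so ancestors are not invented for clearly independent
  branches.
- *Scan order.* Pre-order over parents, sister pairs in lexicographic
  label order, at most one insertion per parent per pass, passes
  repeated to a fixed point. Deterministic and idempotent at the fixed
  point.
- *Sequences for inferred ancestors.* Column-wise parsimony: the symbol
  the sisters share, else the parent's symbol. This minimises implied
  mutations and gives the MRCA/COAR metrics something to compare.
- *Zero-weight edges.* The floor branch can produce d_im = 0. If the
  child is itself an inferred (unobserved) node it is merged into the
  new ancestor; an observed child keeps its weight-0 edge, because it is
  a genuinely sampled, distinct genotype.
- *Guard.* A sister pair whose parent is unobserved and has only those
  two children is skipped: the parent already is their inferred
  ancestor, and inserting another node there would leave a
  single-child unobserved chain.

- *Weights downstream.* When the floor branch fires, d_pi + d_im can
  differ from d_pm; wherever a sequence exists, downstream distances are
  recomputed from sequences rather than read off edited edge weights.

**Depth reduction.** Greedy detach/reattach editing toward a shallower
tree of no greater cost: every non-root node is considered in pre-order
as a subtree to detach, every node outside that subtree as a target in
pre-order, and a move is accepted iff the overall depth strictly
decreases and the cost does not increase (new edge weight = hamming
distance between the new parent and the moved node). First improvement
is applied and the scan restarts; depth is a strictly decreasing
non-negative integer across accepted moves, so termination is
guaranteed. The original description nominates "branching nodes" as
candidates, but its own canonical example moves the grandchild of a
three-node chain — which contains no branching node — so this
implementation considers every non-root node; the acceptance condition
is unchanged. Moves that would leave an unobserved node with fewer than
two children are rejected to preserve the object invariant.

## Tree-comparison metrics

**Tree-based GED** is the minimum number of unit node/edge edits
transforming one tree into the other, computed exactly by depth-first
branch-and-bound over injective node assignments with an admissible
identity-multiset lower bound. Nodes correspond across trees by genotype
label; unobserved nodes have arbitrary labels and correspond by sequence
equality when sequences exist, else never. Exact GED is NP-hard, so
trees beyond `maxNodes` (default 12) are refused rather than silently
approximated — approximation would change the metric. Near-identical
trees resolve essentially instantly at any size because the zero-cost
assignment is found first and the bound prunes the rest; the
parameter-recovery checks therefore raise the bound explicitly.

**Path-based GED** sums, over the union of the two trees' leaves, the
token-level edit distance between the leaf's root-to-node label paths;
leaves absent from one tree contribute their full path length. It is the
more stringent metric, penalising a topological error once per path it
touches. A variant drops unobserved nodes from every path first, which
is useful when inferred ancestors dominate the disagreement.

**MRCA** averages, over all unordered pairs of observed genotypes present
in both trees, the hamming distance between the sequences of the pair's
most recent common ancestors in either tree, normalised by the longer
sequence. All observed pairs — not only leaves — enter the average,
because observed genotypes may be internal. The metric is 0 exactly when
every pairwise ancestor is reconstructed with an identical sequence.

**COAR** evaluates whole evolutionary paths: for each leaf of the
reference tree present in the other tree, its root-to-leaf sequence path
is aligned by Needleman–Wunsch against every root-to-leaf path of the
other tree containing that node, with substitution score
−hamming/length and gap penalty −1 per position; the best score, negated
and normalised by the longer path length, is averaged over the reference
tree's leaves (absent leaves count 1, the worst case). The NW constants
and the max-length normalisation are this package's documented choices
(the original algorithm's supplementary constants are not public); they
are isolated in `alignPaths()`, and with them COAR is provably confined
to [0, 1] since the all-substitution alignment bounds the optimum below
by minus the longer path length. Score ties resolve to the longer
candidate path, i.e. the smaller contribution, deterministically.

## The simulator

`simulateLineage()` emulates a germinal-centre clone as a branching
process: a uniform random root sequence; Poisson(offspringMean) children
per node per generation up to maxGenerations (the root is forced to have
at least one child, so a lineage always exists); Poisson(lambda) point
substitutions per edge, always to a different base, with optional
hotspot weighting (WRC/GYW-style 3-mers; multiplier 1 — off — by
default, since the reconstruction is hotspot-agnostic); Bernoulli
sampling of nodes at observationRate; shifted-geometric abundances with
the configured mean. Edge weights of the truth tree equal the hamming
distance of their endpoints by construction. Everything derives from one
seed.

Defaults (rootLength 350, offspringMean 1.5, lambda 2, maxGenerations 7,
observationRate 0.8, abundanceMean 2.5) are chosen to produce lineages
of a handful to ~100 genotypes with depths mostly between 2 and 7, the
ranges reported for germinal-centre-scale simulations in this
literature. Two caveats, measured rather than assumed: roughly one
lineage in ten dies after the first generation (depth 1), and large
offspring draws can exceed 100 nodes — the defaults emulate the target
ranges, they do not guarantee them.

The *easy regime* (`easyRegime()`) makes recovery exactly identifiable:
every node observed, every edge at least one mutation, every mutation at
a globally fresh site. Pairwise distances are then additive along the
true tree, which makes the truth the unique MST, so the pipeline must
recover it perfectly — the central parameter-recovery property the test
suite checks over dozens of seeded lineages (10–40 nodes each, chosen to
keep the whole suite fast). What passing that check shows is that the
builder, editors and metrics are internally correct; what it does not
show is robustness to what real repertoires add — recurrent and back
mutations, unsampled intermediates, sequencing error, indels (the
simulator places none, by design, so alignment is trivial and the tests
isolate tree logic).

The simulator does not model selection, affinity, class-switching, or
V(D)J-specific root construction: the builder is agnostic to how the
root arose, and a random root exercises it identically.

## Numerical and degenerate-input choices

- All tie-breaks (builder, editors, COAR path choice) are total orders;
  identical inputs give byte-identical outputs, tested end to end.
- Single-genotype inputs yield the single-node tree (cost 0, depth 0);
  two genotypes yield the single root edge.
- Delta pruning never silently repairs disconnection; it reports the
  smallest connecting delta instead.
- Sequence-length mismatches are hard errors everywhere (hamming,
  path alignment, collapsing), never padded or truncated implicitly.
- The builtin aligner is a deterministic centre-star progressive
  Needleman–Wunsch (match 0, mismatch −1, gap −2) adequate for the
  near-identical sequences of one clone; `mafft` can be used through
  `alignSequences(mode = "external")` when higher-fidelity alignment is
  wanted.

## Known limitations

- Position-uniform distances ignore hotspot structure.
- Exact GED is exponential in the worst case; the size bound is a
  guardrail, not a solution.
- The depth-reduction search is greedy first-improvement, not a global
  optimisation over edit sequences.
- Abundance ties beyond the two abundance keys fall back to label order,
  which is arbitrary (though deterministic).
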