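---
title: "Uniform sampling of most parsimonious SCJ labelings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uniform sampling of most parsimonious SCJ labelings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scjgibbs)
```

## The model

A genome over a set of `n` synteny blocks is a conflict-free set of
adjacencies: each block contributes a head and a tail extremity, an
adjacency joins two distinct extremities, and no extremity may be used
twice. Extremities not in any adjacency are telomeres (chromosome ends) and
stay implicit. Linear and circular chromosomes, and any number of them, are
representable; `genome_from_chromosomes()` and `as_chromosomes()` convert
between signed block lists and the adjacency-set form.

The Single Cut or Join (SCJ) model allows two operations: cut one adjacency,
or join two telomeres. Consequently the distance between two genomes over
the same blocks is the size of the symmetric difference of their adjacency
sets — every private adjacency costs exactly one operation. This makes SCJ
the computationally simplest rearrangement model: distances, tree scores and
per-adjacency dynamics all decompose coordinate-wise over the *adjacency
universe* (the distinct adjacencies observed in the input genomes, indexed
in first-seen order for reproducibility). Restricting ancestral genomes to
this universe loses nothing: an adjacency observed nowhere can only increase
the parsimony objective and can be deleted from any labeling without raising
any edge cost.

### Small parsimony per adjacency

Given a rooted strictly binary tree with genomes at the leaves, encode each
genome as a 0/1 vector over the universe. For each coordinate the package
runs two classic dynamic programs on the presence/absence character:

* **Fitch**: bottom-up candidate sets `B(v)` (intersection of the children's
  sets when nonempty, else union), then top-down assignment. On the binary
  alphabet the only ambiguity is at a tied root, where the *canonical*
  labeling always picks absence; with this tie-break the per-coordinate
  assignments are simultaneously conflict-free at every vertex, so the
  canonical labeling is a most parsimonious *valid* labeling.
* **Sankoff–Rousseau**: subtree costs `s(v, k)` for writing state
  `k ∈ {0, 1}` at `v`, with `s(v,k) = Σ_children min(s(u,k), s(u,1−k)+1)`.
  Its argmin traces describe *all* per-coordinate optima, including ones
  Fitch cannot produce — but some of those are invalid as genomes, which is
  exactly why sampling needs care.

A useful identity connects the two: `B(v) = {0,1}` exactly when
`s(v,0) = s(v,1)`. The test suite checks both directions on random trees.

## The Gibbs sampler

The target distribution is uniform over all most parsimonious valid
labelings. One step:

1. draw a coordinate `i` uniformly from the universe;
2. run the Sankoff–Rousseau recursion on coordinate `i`'s leaf states;
3. build a metagraph over states `(v, k)`: state `(v, 1)` exists only if
   writing adjacency `i` into the genome at `v` keeps it conflict-free given
   the *current* values of all other coordinates (both extremities of
   adjacency `i` free, ignoring `i` itself); leaves contribute only their
   observed state. Edges connect a child state to a parent state when the
   child attains the minimum in the recursion;
4. weight each state by the number of valid optimal sub-assignments below
   it: leaves weigh 1, and an internal state's weight is the product over
   child sides of the summed in-neighbor weights;
5. draw the root state among valid minimum-cost states proportionally to
   weight, then propagate down by weighted draws, and write the chosen
   states into coordinate `i`.

This is a textbook enumeration-DP-plus-backward-draw, so the conditional is
*exactly* uniform over the labelings that are optimal, valid, and agree with
the current one off coordinate `i`. The package verifies this against a
brute-force enumeration of that conditional support (`enumerate_compatible()`)
on small instances.

**Root-state support.** Taken literally, step 5's "choose randomly from the
two root states" would admit a root state whose cost exceeds
`min_k s(root, k)`; the resulting labeling would not be most parsimonious.
Because the canonical labeling attains the per-coordinate minimum in every
coordinate simultaneously, the global optimum equals the sum of
per-coordinate minima, so every optimal labeling attains every coordinate's
minimum. The sampler therefore restricts the root draw to minimum-cost
states. This is a deliberate tightening; the oracle-equivalence tests are
the arbiter that the restricted conditional is the correct one.

**Irreducibility.** The chain moves between optimal labelings one
coordinate at a time, and validity constraints couple coordinates, so
irreducibility is not obvious. `canonicalize_labeling()` implements the
constructive argument as an executable, asserted procedure: phase 1 removes
adjacencies present where `B = {0}` (minimal-height violations first),
re-propagating below the vertex by Fitch; phase 2 symmetrically adds
adjacencies absent where `B = {1}`; phase 3 clears each adjacency from the
root-containing component on which `B ≡ {0,1}`. Every move is a single
admissible Gibbs step, checked for validity and score preservation, and the
procedure must land exactly on the canonical labeling. Since moves are
reversible, any two optimal labelings are connected through the canonical
one. Tests canonicalize both enumerated optima and chain samples.

## Optimal SCJ medians

For genomes `G1..Gk`, any optimal median contains every adjacency present in
more than half of the genomes (two conflicting adjacencies cannot both hold
a strict majority, so this *majority genome* is valid — and for odd `k` it
is the unique optimal median). For even `k`, adjacencies present in exactly
half form the *conflict graph* on extremities. No extremity can lie in more
than two half-frequency adjacencies, so every vertex has degree at most 2
and the graph decomposes into isolated vertices, paths and cycles. Optimal
medians are exactly: majority set ∪ one matching of the conflict graph.

Matchings (including the empty one) are counted by the linear recurrence
`M(n) = M(n−1) + M(n−2)` with `M(0) = 1`, `M(1) = 2` on a path of `n` edges
(shifted Fibonacci numbers) and by the Lucas numbers
`L(n) = M(n−1) + M(n−3)` on a cycle; the median count is the product over
components. The recurrences — rather than a closed-form summation — are the
implementation, validated against brute-force matching enumeration up to 12
edges and against the Fibonacci/Lucas closed forms up to 20.
`sample_scj_median()` draws a uniform matching per component by backward
simulation of the same recurrence; `enumerate_scj_medians()` lists all
medians below a cap.

## Synthetic data

The generators make every claim testable without external genome data:

* `random_genome(n_blocks, join_prob)` shuffles the `2n` extremities into a
  random pairing and keeps each candidate pair with probability `join_prob`
  (default 0.5, giving a realistic mix of adjacencies and telomeres; 0 is
  fully fragmented, 1 a fully joined genome). The construction touches each
  extremity once, so validity is guaranteed, not checked.
* `random_scj_op()` applies one operation chosen uniformly among all
  available cuts and telomere-pair joins; the result is always at distance
  exactly 1.
* `evolve_genomes(tree, root, ops_per_edge)` applies a
  Poisson(`ops_per_edge`) number of operations along each edge, top-down,
  and returns the full truth. A homogeneous Poisson process is deliberate:
  the fixtures need plausible correlation structure between related leaves,
  not biological realism — there is no rate heterogeneity, no
  operation-type bias, no length model. Consequently, passing tests
  demonstrate correctness of the algorithms on SCJ-like data, not fidelity
  of SCJ to real genome evolution (the model itself ignores rearrangement
  mechanism entirely).

## Numerical and design choices

* **Infinity.** Sankoff tables use the integer sentinel `1e9` with
  saturating arithmetic; attainable costs are bounded by the edge count, so
  the sentinel can never be confused with a real cost.
* **Weights.** Metagraph weights are doubles holding exact integers.
  Per-coordinate solution counts are bounded by 2^(internal nodes), far
  below the 2^53 exactness limit for any tractable tree; a guard aborts if
  a weight approaches it. Weighted draws use `sample.int(prob =)` on those
  exact integer weights.
* **Tie-breaking.** No tie is ever resolved by positional order: all ties
  flow into the weighted random draw. The only deterministic tie-break in
  the package is the canonical labeling's absence-at-root rule, which is
  part of the definition.
* **Determinism.** Adjacency keys order their two extremities by C-locale
  string order; the universe uses first-seen order over leaves in tree
  order; enumeration outputs are ordered by binary encoding. Chains are
  bit-reproducible from their seed.
* **Degenerate inputs.** An empty adjacency universe (all-telomere leaf
  genomes) yields a zero-score constant chain; a zero-step chain records
  exactly the canonical labeling; trees must be strictly binary with at
  least two named, distinct leaves — anything else is rejected up front
  with the offending node named.
* **Autocorrelation.** Traces use the biased (divide-by-`n`) estimator, the
  common MCMC convention; a zero-variance trace reports 0 at positive lags
  so constant edges read as instantly mixed rather than undefined.
* **Score conservation as an invariant.** The chain can only move between
  most parsimonious labelings, so the per-sample sum of edge lengths is
  constant; `run_gibbs()` asserts it at every recorded sample and
  diagnostics re-check it.

## Problem sizes used in the checks

The test suite exercises: exhaustive oracle comparisons on 4-leaf instances
with universes up to ~10 adjacencies (solution sets enumerated completely);
a 200,000-step chain (thinned every 10) against an enumerated 16-element
solution set for the uniformity check; 20 (state, coordinate) pairs with
10,000 conditional draws each; a 100,000-step, 8-leaf, 20-block run for
trace and autocorrelation behaviour; and 100-instance sweeps for the median
counting, degree-bound and Fitch/Sankoff equivalence properties. These sizes
were chosen so the whole suite enumerates its ground truth exactly where it
claims to.

## Limitations

* The sampler targets most parsimonious *labelings*; it does not sample
  rearrangement *scenarios* along edges, and no mixing-time bound is proved
  — autocorrelation diagnostics are evidence, not a guarantee.
* Counts use exact double arithmetic (below 2^53); truly enormous conflict
  graphs would need big integers.
* Strictly binary rooted trees only; multifurcations are rejected rather
  than resolved, because every recursion and the irreducibility argument
  assume two children per internal node.
* The SCJ model itself treats every cut and join as equally likely and
  ignores chromosome-level constraints; conclusions about real genomes
  should treat SCJ scores as a lower-bound-style summary, not a mechanistic
  model.
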