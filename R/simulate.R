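# Seeded generators: random genomes, single SCJ operations, and evolution
# along a tree. Every function uses the current RNG state; wrap calls in
# set.seed() (or use the seed arguments of the top-level drivers) for
# bit-reproducible fixtures.

#' Generate a random genome
#'
#' Shuffles the 2n extremities of `n_blocks` blocks into a random perfect
#' pairing and keeps each candidate pair as an adjacency with probability
#' `join_prob`. The construction touches every extremity at most once, so
#' the result is always conflict-free; `join_prob = 0` gives the fully
#' fragmented genome (all telomeres), `join_prob = 1` a perfect pairing.
#'
#' @param n_blocks Number of synteny blocks (named `"1"..."n"`).
#' @param join_prob Probability of keeping each candidate adjacency
#'   (default 0.5, an even mix of adjacencies and telomeres).
#' @param name Genome name.
#' @return An `scj_genome`.
#' @export
random_genome <- function(n_blocks, join_prob = 0.5, name = "random") {
  stopifnot(n_blocks >= 1L, join_prob >= 0, join_prob <= 1)
  blocks <- as.character(seq_len(n_blocks))
  exts <- c(extremity(blocks, "t"), extremity(blocks, "h"))
  exts <- sample(exts)
  first <- exts[seq(1L, length(exts), by = 2L)]
  second <- exts[seq(2L, length(exts), by = 2L)]
  keep <- stats::runif(length(first)) < join_prob
  adjs <- if (any(keep)) adjacency(first[keep], second[keep]) else character()
  genome(name, blocks, adjs)
}

#' Apply one random SCJ operation
#'
#' Chooses uniformly among all available operations — cutting one existing
#' adjacency, or joining two of the currently free extremities (telomeres) —
#' and applies it. The result is a valid genome at SCJ distance exactly 1
#' from the input.
#'
#' @param g An `scj_genome`.
#' @return An `scj_genome`.
#' @export
random_scj_op <- function(g) {
  stopifnot(inherits(g, "scj_genome"))
  used <- as.vector(adj_ends(g$adjacencies))
  free <- setdiff(c(extremity(g$blocks, "t"), extremity(g$blocks, "h")), used)
  n_cut <- length(g$adjacencies)
  n_join <- choose(length(free), 2L)
  if (n_cut + n_join == 0) {
    abort("no SCJ operation available (no adjacency and fewer than two telomeres).")
  }
  pick <- stats::runif(1) * (n_cut + n_join)
  if (pick < n_cut) {
    cut <- sample.int(n_cut, 1L)
    genome(g$name, g$blocks, g$adjacencies[-cut])
  } else {
    pair <- sample(free, 2L)
    genome(g$name, g$blocks, c(g$adjacencies, adjacency(pair[1L], pair[2L])))
  }
}

#' Simulate SCJ evolution along a tree
#'
#' Starting from `root_genome` at the root, applies an independent
#' Poisson(`ops_per_edge`) number of random SCJ operations along each edge,
#' top-down. Returns the full truth: the genome at every vertex and the
#' number of operations applied per edge (an upper bound on the realized
#' per-edge SCJ distance, since operations can cancel).
#'
#' @param tree An `scj_tree`.
#' @param root_genome Genome at the root.
#' @param ops_per_edge Poisson mean of the number of operations per edge.
#' @return An `scj_evolution`: list with `tree`, `genomes` (list over all
#'   vertices, named by vertex label), `leaf_genomes` (named list for
#'   [bind_genomes()]), and `ops` (tibble `edge`, `n_ops`, `scj_length`).
#' @export
evolve_genomes <- function(tree, root_genome, ops_per_edge) {
  stopifnot(inherits(tree, "scj_tree"), inherits(root_genome, "scj_genome"),
            ops_per_edge >= 0)
  genomes <- vector("list", tree$n_vertex)
  genomes[[tree$root]] <- genome(tree$labels[tree$root], root_genome$blocks,
                                 root_genome$adjacencies)
  n_ops <- integer(nrow(tree$edges))
  for (r in seq_len(nrow(tree$edges))) {
    p <- tree$edges[r, 1L]
    v <- tree$edges[r, 2L]
    g <- genomes[[p]]
    k <- stats::rpois(1L, ops_per_edge)
    for (j in seq_len(k)) {
      g <- random_scj_op(g)
    }
    genomes[[v]] <- genome(tree$labels[v], g$blocks, g$adjacencies)
    n_ops[r] <- k
  }
  leaf <- genomes[seq_len(tree$n_tip)]
  names(leaf) <- tree$labels[seq_len(tree$n_tip)]
  realized <- vapply(seq_len(nrow(tree$edges)), function(r) {
    scj_distance(genomes[[tree$edges[r, 1L]]], genomes[[tree$edges[r, 2L]]])
  }, numeric(1))
  structure(
    list(
      tree = tree,
      genomes = stats::setNames(genomes, tree$labels),
      leaf_genomes = leaf,
      ops = tibble(edge = edge_names(tree), n_ops = n_ops,
                   scj_length = as.integer(realized))
    ),
    class = "scj_evolution"
  )
}

#' Random balanced tree topology
#'
#' Convenience wrapper for test fixtures: a random rooted binary topology on
#' `n_leaves` labeled leaves (via `ape::rtree`).
#'
#' @param n_leaves Number of leaves (labeled `L1...Ln`).
#' @return An `scj_tree`.
#' @export
random_topology <- function(n_leaves) {
  phy <- ape::rtree(n_leaves, rooted = TRUE, tip.label = paste0("L", seq_len(n_leaves)))
  phy$edge.length <- NULL
  phy$node.label <- NULL
  read_tree_newick(text = ape::write.tree(phy))
}
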