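# Shared fixtures, all built in code.

# 4-leaf instance over one adjacency with leaf pattern ((1,1),(0,0)):
# the smallest instance with two most parsimonious labelings (root 0 or 1).
toy_instance <- function() {
  a <- adjacency("1h", "2t")
  bind_genomes(
    read_tree_newick("((A,B)u1,(C,D)u2)root;"),
    list(
      A = genome("A", 1:2, a),
      B = genome("B", 1:2, a),
      C = genome("C", 1:2),
      D = genome("D", 1:2)
    )
  )
}

# seeded instance grown by SCJ evolution along a fixed 4-leaf topology
random_evolved_instance <- function(seed, n_blocks = 5, ops = 3,
                                    newick = "((A,B),(C,D));") {
  tree <- read_tree_newick(newick)
  set.seed(seed)
  root <- random_genome(n_blocks, 0.5, name = "root")
  ev <- evolve_genomes(tree, root, ops)
  bind_genomes(tree, ev$leaf_genomes)
}

# named random genome collection over a shared block set
random_genome_set <- function(n_genomes, n_blocks, join_prob = 0.5) {
  gs <- lapply(seq_len(n_genomes), function(j) {
    random_genome(n_blocks, join_prob, name = paste0("g", j))
  })
  stats::setNames(gs, vapply(gs, `[[`, character(1), "name"))
}

labeling_internal_key <- function(instance, lab) {
  internal <- (instance$tree$n_tip + 1L):instance$tree$n_vertex
  paste(lab[internal, , drop = FALSE], collapse = "")
}
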