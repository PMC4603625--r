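test_that("Newick parsing builds strictly binary rooted trees", {
  tr <- read_tree_newick("((A,B),(C,D));")
  expect_s3_class(tr, "scj_tree")
  expect_identical(tr$n_tip, 4L)
  expect_identical(tr$n_vertex, 7L)
  expect_identical(sort(tr$labels[1:4]), c("A", "B", "C", "D"))
  # auto-named internal nodes in preorder
  expect_identical(tr$labels[tr$root], "N1")
  expect_setequal(tr$labels[5:7], c("N1", "N2", "N3"))
  # every internal vertex has exactly two children; edges = 2|L| - 2
  expect_identical(nrow(tr$edges), 6L)
  expect_true(all(!is.na(tr$children[5:7, ])))
})

test_that("non-binary and malformed trees are rejected with the offending node", {
  expect_error(read_tree_newick("(A,B,C);"), "multifurcation")
  expect_error(read_tree_newick("((A,B),(C,D),E);"), "multifurcation")
  expect_error(read_tree_newick("((A,B));"), "unary")
  expect_error(read_tree_newick("((A,B),(A,C));"), "duplicate leaf name: A")
  expect_error(read_tree_newick("this is not newick"), "parse failed")
})

test_that("named internal nodes and branch lengths are handled", {
  tr <- read_tree_newick("((A:0.1,B:0.2)u1:0.3,(C,D)u2)root;")
  expect_identical(tr$labels[tr$root], "root")
  expect_setequal(tr$labels[5:7], c("root", "u1", "u2"))
})

test_that("binding checks leaf coverage and block homogeneity", {
  tr <- read_tree_newick("(A,B);")
  g1 <- genome("A", 1:2, adjacency("1h", "2t"))
  g2 <- genome("B", 1:2)
  inst <- bind_genomes(tr, list(A = g1, B = g2))
  expect_s3_class(inst, "scj_instance")
  expect_identical(inst$universe$keys, adjacency("1h", "2t"))
  expect_error(bind_genomes(tr, list(A = g1)), "no genome for leaf: B")
  expect_error(bind_genomes(tr, list(A = g1, B = g2, X = g2)), "matches no leaf")
  g3 <- genome("B", 1:3)
  expect_error(bind_genomes(tr, list(A = g1, B = g3)), "different block set")
})

test_that("tree_score sums edge distances and decomposes per coordinate", {
  inst <- toy_instance()
  lab <- canonical_labeling(inst)
  expect_identical(tree_score(inst, lab), 1L)
  # all-identical labeling scores 0
  tr2 <- read_tree_newick("(A,B);")
  g <- genome("x", 1:2, adjacency("1h", "2t"))
  inst2 <- bind_genomes(tr2, list(A = genome("A", g$blocks, g$adjacencies),
                                  B = genome("B", g$blocks, g$adjacencies)))
  lab2 <- canonical_labeling(inst2)
  expect_identical(tree_score(inst2, lab2), 0L)
  # cherry with leaves at distance 2, root equal to one leaf
  gB <- genome("B", 1:2, adjacency("1h", "2h"))
  inst3 <- bind_genomes(tr2, list(A = genome("A", 1:2, adjacency("1h", "2t")), B = gB))
  lab3 <- canonical_labeling(inst3)
  lab3["N1", ] <- inst3$leaf_matrix["A", ]
  expect_identical(tree_score(inst3, lab3), 2L)
  # per-coordinate decomposition on a random instance
  inst4 <- random_evolved_instance(21)
  lab4 <- canonical_labeling(inst4)
  e <- inst4$tree$edges
  per_coord <- vapply(seq_along(inst4$universe$keys), function(i) {
    sum(abs(lab4[e[, 1L], i] - lab4[e[, 2L], i]))
  }, numeric(1))
  expect_identical(tree_score(inst4, lab4), as.integer(sum(per_coord)))
})
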