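# B set codes: 1 = {0}, 2 = {1}, 3 = {0,1}

test_that("Fitch bottom-up applies intersection-else-union", {
  cherry <- read_tree_newick("(A,B);")
  expect_identical(fitch_bottom_up(cherry, c(1L, 0L))[cherry$root], 3L)
  expect_identical(fitch_bottom_up(cherry, c(1L, 1L))[cherry$root], 2L)
  tr <- read_tree_newick("((A,B)u1,(C,D)u2)root;")
  chars <- stats::setNames(c(1L, 1L, 0L, 0L), c("A", "B", "C", "D"))
  B <- fitch_bottom_up(tr, chars[tr$labels[1:4]])
  expect_identical(B[match("u1", tr$labels)], 2L)
  expect_identical(B[match("u2", tr$labels)], 1L)
  expect_identical(B[tr$root], 3L)
})

test_that("Fitch top-down prefers absence at a tied root and propagates", {
  tr <- read_tree_newick("((A,B)u1,(C,D)u2)root;")
  chars <- stats::setNames(c(1L, 1L, 0L, 0L), c("A", "B", "C", "D"))
  B <- fitch_bottom_up(tr, chars[tr$labels[1:4]])
  f <- fitch_top_down(tr, B)
  expect_identical(f[tr$root], 0L)
  expect_identical(f[match("u1", tr$labels)], 1L)
  expect_identical(f[match("u2", tr$labels)], 0L)
  # forced root when B(root) is a singleton
  B2 <- fitch_bottom_up(tr, c(1L, 1L, 1L, 1L))
  expect_identical(fitch_top_down(tr, B2)[tr$root], 1L)
})

test_that("Sankoff recursion matches hand-evaluated tables", {
  INF <- scjgibbs:::INF
  cherry <- read_tree_newick("(A,B);")
  s <- sankoff(cherry, c(1L, 0L))
  expect_identical(s[1L, ], c(s0 = INF, s1 = 0L))
  expect_identical(unname(s[cherry$root, ]), c(1L, 1L))
  expect_identical(coordinate_min(s, cherry), 1L)

  tr <- read_tree_newick("((A,B)u1,(C,D)u2)root;")
  chars <- stats::setNames(c(1L, 1L, 0L, 0L), c("A", "B", "C", "D"))
  s2 <- sankoff(tr, chars[tr$labels[1:4]])
  expect_identical(unname(s2["u1", ]), c(2L, 0L))
  expect_identical(unname(s2["u2", ]), c(0L, 2L))
  expect_identical(unname(s2["root", ]), c(1L, 1L))
  # constant character costs nothing
  s3 <- sankoff(tr, c(0L, 0L, 0L, 0L))
  expect_identical(coordinate_min(s3, tr), 0L)
})

test_that("candidate-set ties coincide exactly with Sankoff cost ties", {
  # both directions of the B(v)={0,1} <=> s(v,0)=s(v,1) equivalence
  set.seed(5150)
  for (rep in 1:60) {
    n_leaves <- sample(3:7, 1L)
    tr <- random_topology(n_leaves)
    chars <- sample(0:1, n_leaves, replace = TRUE)
    B <- fitch_bottom_up(tr, chars)
    s <- sankoff(tr, chars)
    expect_identical(B == 3L, unname(s[, 1L] == s[, 2L]))
  }
})

test_that("canonical labeling is valid and attains the per-coordinate optimum sum", {
  inst <- toy_instance()
  lab <- canonical_labeling(inst)
  expect_identical(unname(lab["root", 1L]), 0L)
  expect_identical(unname(lab["u1", 1L]), 1L)
  expect_identical(unname(lab["u2", 1L]), 0L)
  expect_identical(tree_score(inst, lab), 1L)

  for (seed in c(3, 12, 27, 44, 58)) {
    inst <- random_evolved_instance(seed)
    lab <- canonical_labeling(inst)
    expect_true(scjgibbs:::labeling_is_valid(inst, lab))
    s <- scjgibbs:::sankoff_all(inst)
    per_min <- pmin(s$s0[inst$tree$root, ], s$s1[inst$tree$root, ])
    expect_identical(tree_score(inst, lab), as.integer(sum(per_min)))
  }
})

test_that("identical leaf genomes give a zero-score constant labeling", {
  g <- genome("x", 1:3, c(adjacency("1h", "2t"), adjacency("2h", "3t")))
  tr <- read_tree_newick("((A,B),(C,D));")
  gs <- lapply(c("A", "B", "C", "D"), function(nm) genome(nm, g$blocks, g$adjacencies))
  inst <- bind_genomes(tr, stats::setNames(gs, c("A", "B", "C", "D")))
  lab <- canonical_labeling(inst)
  expect_identical(tree_score(inst, lab), 0L)
  expect_true(all(apply(lab, 2L, function(col) length(unique(col)) == 1L)))
})

test_that("canonical labeling stays valid when per-coordinate optima conflict", {
  # genomes whose universes contain conflicting adjacencies; validity of the
  # canonical output must hold regardless
  set.seed(404)
  for (rep in 1:25) {
    inst <- random_evolved_instance(sample.int(10000, 1L), n_blocks = 4, ops = 4)
    lab <- canonical_labeling(inst)
    expect_true(scjgibbs:::labeling_is_valid(inst, lab))
  }
})

test_that("fitch_table reports B and s consistently", {
  inst <- toy_instance()
  ft <- fitch_table(inst)
  expect_identical(nrow(ft), 7L)
  expect_identical(ft$B[ft$vertex == "root"], "01")
  expect_identical(ft$s0[ft$vertex == "root"], 1L)
  expect_identical(ft$s1[ft$vertex == "root"], 1L)
  expect_true(is.na(ft$s0[ft$vertex == "A"]))
})
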