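test_that("metagraph keeps both root states with unit weights on the toy instance", {
  inst <- toy_instance()
  lab <- canonical_labeling(inst)
  M <- scjgibbs:::build_metagraph(inst, lab, 1L)
  tr <- inst$tree
  root <- tr$root
  u1 <- match("u1", tr$labels)
  u2 <- match("u2", tr$labels)
  # with a single adjacency nothing can conflict: all internal states present
  expect_true(all(M$present0[c(root, u1, u2)]))
  expect_true(all(M$present1[c(root, u1, u2)]))
  # two optimal labelings in total, one through each root state
  expect_identical(M$m0[root], 1)
  expect_identical(M$m1[root], 1)
  # in-edges of (root, 0): u1 contributes only state 1, u2 only state 0
  expect_identical(M$side_weight(u1, 0L), M$m1[u1])
  expect_identical(M$side_weight(u2, 0L), M$m0[u2])
  expect_identical(unname(M$s[u1, ]), c(2L, 0L))
})

test_that("a conflicting adjacency at a vertex removes its present-state node", {
  # two conflicting adjacencies shared by different leaf pairs
  a <- adjacency("1h", "2t")
  b <- adjacency("1h", "2h")
  tr <- read_tree_newick("((A,B)u1,(C,D)u2)root;")
  inst <- bind_genomes(tr, list(
    A = genome("A", 1:2, a), B = genome("B", 1:2, a),
    C = genome("C", 1:2, b), D = genome("D", 1:2, b)
  ))
  lab <- canonical_labeling(inst)
  ia <- match(a, inst$universe$keys)
  ib <- match(b, inst$universe$keys)
  u1 <- match("u1", tr$labels)
  # canonical puts a at u1; resampling b must see (u1, present-b) as invalid
  expect_identical(unname(lab[u1, ia]), 1L)
  M <- scjgibbs:::build_metagraph(inst, lab, ib)
  expect_false(M$present1[u1])
  expect_true(M$present0[u1])
})

test_that("resampling is forced when the root minimum is unique", {
  tr <- read_tree_newick("((A,B)u1,(C,D)u2)root;")
  a <- adjacency("1h", "2t")
  inst <- bind_genomes(tr, list(
    A = genome("A", 1:2, a), B = genome("B", 1:2, a),
    C = genome("C", 1:2, a), D = genome("D", 1:2)
  ))
  lab <- canonical_labeling(inst)
  # 3 of 4 leaves carry the adjacency: presence everywhere is the unique optimum
  set.seed(1)
  for (r in 1:10) {
    out <- resample_coordinate(inst, lab, 1L)
    expect_identical(unname(out[5:7, 1L]), unname(lab[5:7, 1L]))
  }
})

test_that("the toy-instance conditional is uniform over both root states", {
  inst <- toy_instance()
  lab <- canonical_labeling(inst)
  set.seed(8)
  roots <- replicate(4000, unname(resample_coordinate(inst, lab, 1L)["root", 1L]))
  expect_gt(stats::binom.test(sum(roots), 4000, 0.5)$p.value, 1e-4)
})

test_that("gibbs steps preserve validity, score and off-coordinate states", {
  inst <- random_evolved_instance(9)
  lab <- canonical_labeling(inst)
  score <- tree_score(inst, lab)
  set.seed(10)
  for (step in 1:200) {
    i <- sample.int(length(inst$universe$keys), 1L)
    new <- resample_coordinate(inst, lab, i)
    expect_identical(tree_score(inst, new), score)
    expect_identical(new[, -i, drop = FALSE], lab[, -i, drop = FALSE])
    lab <- new
  }
  expect_true(scjgibbs:::labeling_is_valid(inst, lab))
})

test_that("resampling support matches the oracle conditional exactly", {
  for (seed in c(2, 9, 11)) {
    inst <- random_evolved_instance(seed)
    set.seed(seed + 1000)
    lab <- canonical_labeling(inst)
    for (w in 1:30) lab <- gibbs_step(inst, lab)
    internal <- (inst$tree$n_tip + 1L):inst$tree$n_vertex
    for (i in seq_along(inst$universe$keys)) {
      support <- vapply(enumerate_compatible(inst, lab, i),
                        paste, character(1), collapse = "")
      draws <- replicate(400, paste(resample_coordinate(inst, lab, i)[internal, i],
                                    collapse = ""))
      expect_true(all(draws %in% support))
      if (length(support) > 1L) {
        expect_setequal(unique(draws), support)
      }
    }
  }
})

test_that("a zero-step chain records exactly the canonical labeling", {
  inst <- toy_instance()
  ch <- run_gibbs(inst, steps = 0L, seed = 4L)
  expect_length(ch$samples, 1L)
  canon <- canonical_labeling(inst)
  expect_identical(unname(ch$samples[[1L]]), unname(canon[5:7, , drop = FALSE]))
})

test_that("identical leaves give constant samples with zero edge lengths", {
  g <- genome("x", 1:2, adjacency("1h", "2t"))
  tr <- read_tree_newick("((A,B),(C,D));")
  inst <- bind_genomes(tr, stats::setNames(
    lapply(c("A", "B", "C", "D"), function(nm) genome(nm, g$blocks, g$adjacencies)),
    c("A", "B", "C", "D")
  ))
  ch <- run_gibbs(inst, steps = 50L, thin = 5L, seed = 2L)
  expect_identical(ch$score, 0L)
  expect_true(all(ch$edge_lengths == 0L))
  keys <- vapply(ch$samples, scjgibbs:::labeling_key, character(1))
  expect_length(unique(keys), 1L)
})

test_that("chains are reproducible from the seed and respect thin/burn-in", {
  inst <- random_evolved_instance(5)
  ch1 <- run_gibbs(inst, steps = 300L, thin = 10L, burn_in = 100L, seed = 33L)
  ch2 <- run_gibbs(inst, steps = 300L, thin = 10L, burn_in = 100L, seed = 33L)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$edge_lengths, ch2$edge_lengths)
  expect_identical(ch1$sample_steps, seq(110L, 300L, by = 10L))
  ch3 <- run_gibbs(inst, steps = 300L, thin = 10L, burn_in = 100L, seed = 34L)
  expect_false(identical(ch1$samples, ch3$samples))
})

test_that("tidy/glance expose traces and chain summary", {
  inst <- random_evolved_instance(5)
  ch <- run_gibbs(inst, steps = 100L, thin = 10L, seed = 3L)
  td <- generics::tidy(ch)
  expect_identical(nrow(td), 10L * nrow(inst$tree$edges))
  sums <- tapply(td$length, td$sample, sum)
  expect_true(all(sums == ch$score))
  gl <- generics::glance(ch)
  expect_identical(gl$score, ch$score)
  expect_identical(gl$n_samples, 10L)
})
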