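test_that("conflict graph counts half-frequency and majority adjacencies", {
  a <- adjacency("1h", "2t")
  b <- adjacency("1h", "2h")
  g1 <- genome("g1", 1:2, a)
  g2 <- genome("g2", 1:2, b)
  cg <- conflict_graph(list(g1, g2))
  expect_setequal(cg$half, c(a, b))
  expect_identical(cg$majority, character(0))
  expect_identical(max(cg$degree), 2L)  # 1h lies on both half edges
  dec <- decompose_conflict_graph(cg)
  expect_identical(dec$kind[dec$n_edges == 2L], "path")

  # odd collections have no half-frequency edges
  g3 <- genome("g3", 1:2)
  cg3 <- conflict_graph(list(g1, g1, g3))
  expect_identical(cg3$half, character(0))
  expect_identical(cg3$majority, a)

  # an identical pair: majority = shared adjacencies, empty edge set
  cgp <- conflict_graph(list(g1, g1))
  expect_identical(cgp$half, character(0))
  expect_identical(cgp$majority, a)
})

test_that("a closed chain of half-frequency adjacencies is decomposed as a cycle", {
  # two genomes partitioning the 4 adjacencies of a 2-block circle
  g1 <- genome("g1", 1:2, c(adjacency("1h", "2t"), adjacency("2h", "1t")))
  g2 <- genome("g2", 1:2, c(adjacency("1h", "2h"), adjacency("1t", "2t")))
  cg <- conflict_graph(list(g1, g2))
  dec <- decompose_conflict_graph(cg)
  expect_identical(dec$kind[dec$n_edges > 0L], "cycle")
  expect_identical(dec$n_edges[dec$kind == "cycle"], 4L)
  expect_identical(count_scj_medians(list(g1, g2)), 7)
})

test_that("matching counts follow the path/cycle recurrences and brute force", {
  expect_identical(count_matchings_path(0L), 1)
  expect_identical(count_matchings_path(1L), 2)
  expect_identical(count_matchings_path(2L), 3)
  expect_identical(count_matchings_cycle(3L), 4)
  expect_identical(count_matchings_cycle(4L), 7)
  for (n in 1:12) {
    pe <- cbind(seq_len(n), seq_len(n) + 1L)
    expect_identical(count_matchings_path(n), count_matchings_bruteforce(pe))
    if (n >= 3L) {
      ce <- cbind(seq_len(n), c(seq_len(n - 1L) + 1L, 1L))
      expect_identical(count_matchings_cycle(n), count_matchings_bruteforce(ce))
    }
  }
  # closed forms: path counts are shifted Fibonacci, cycle counts Lucas
  phi <- (1 + sqrt(5)) / 2
  fib <- function(n) round((phi^n - (-phi)^(-n)) / sqrt(5))
  for (n in 1:20) {
    expect_identical(count_matchings_path(n), fib(n + 2))
    if (n >= 3L) {
      expect_identical(count_matchings_cycle(n), fib(n - 1) + fib(n + 1))
    }
  }
})

test_that("median counts agree with brute force on random even collections", {
  set.seed(301)
  for (rep in 1:25) {
    gs <- random_genome_set(4, 5)
    expect_identical(count_scj_medians(gs),
                     as.numeric(length(bruteforce_medians(gs)$medians)))
  }
})

test_that("odd collections have a unique median: the majority genome", {
  set.seed(302)
  for (rep in 1:20) {
    gs <- random_genome_set(3, 5)
    expect_identical(count_scj_medians(gs), 1)
    bf <- bruteforce_medians(gs)
    expect_length(bf$medians, 1L)
    expect_identical(bf$medians[[1L]]$adjacencies,
                     majority_median(gs)$adjacencies)
  }
})

test_that("enumerated medians are exactly the brute-force optima", {
  a <- adjacency("1h", "2t")
  b <- adjacency("1h", "2h")
  gs <- list(genome("g1", 1:2, a), genome("g2", 1:2, b))
  meds <- enumerate_scj_medians(gs)
  expect_length(meds, 3L)
  keys <- sort(vapply(meds, function(g) paste(g$adjacencies, collapse = ","), ""))
  expect_identical(unname(keys), sort(c("", a, b), method = "radix"))

  set.seed(303)
  for (rep in 1:15) {
    gs <- random_genome_set(4, 4)
    meds <- enumerate_scj_medians(gs)
    bf <- bruteforce_medians(gs)
    med_keys <- sort(vapply(meds, function(g) paste(g$adjacencies, collapse = ","), ""))
    bf_keys <- sort(vapply(bf$medians, function(g) paste(g$adjacencies, collapse = ","), ""))
    expect_identical(unname(med_keys), unname(bf_keys))
  }
  expect_error(enumerate_scj_medians(gs, cap = 0), "cap")
})

test_that("majority median is always a valid genome", {
  set.seed(304)
  for (rep in 1:200) {
    k <- sample(c(3:6), 1L)
    gs <- random_genome_set(k, 5)
    m <- majority_median(gs)
    expect_s3_class(m, "scj_genome")  # constructor enforces conflict-freeness
  }
})

test_that("sampled medians are optimal and uniform on a small instance", {
  a <- adjacency("1h", "2t")
  b <- adjacency("1h", "2h")
  gs <- list(genome("g1", 1:2, a), genome("g2", 1:2, b))
  bf <- bruteforce_medians(gs)
  bf_keys <- vapply(bf$medians, function(g) paste(g$adjacencies, collapse = ","), "")
  set.seed(305)
  draws <- replicate(3000, paste(sample_scj_median(gs)$adjacencies, collapse = ","))
  expect_true(all(draws %in% bf_keys))
  counts <- table(factor(draws, levels = bf_keys))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("sampled medians attain the brute-force optimum on random even collections", {
  set.seed(306)
  for (rep in 1:15) {
    gs <- random_genome_set(4, 4)
    bf <- bruteforce_medians(gs)
    m <- sample_scj_median(gs)
    tot <- sum(vapply(gs, scj_distance, numeric(1), g2 = m))
    expect_identical(tot, as.numeric(bf$score))
  }
})
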