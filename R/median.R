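# Optimal SCJ medians of a genome collection.
#
# An optimal median contains every adjacency present in more than half of
# the genomes, plus any conflict-free subset of the adjacencies present in
# exactly half (possible only for an even number of genomes). The
# half-frequency adjacencies form the conflict graph on extremities; no
# extremity can lie in more than two of them, so the graph decomposes into
# isolated vertices, paths and cycles, conflict-free subsets are exactly
# matchings, and the median count is a product of per-component matching
# counts (Fibonacci numbers on paths, Lucas numbers on cycles).

as_genome_list <- function(genomes) {
  if (inherits(genomes, "scj_genome")) {
    return(list(genomes))
  }
  if (is.data.frame(genomes)) {
    return(genomes_from_table(genomes))
  }
  stopifnot(is.list(genomes), all(vapply(genomes, inherits, logical(1), "scj_genome")))
  genomes
}

check_shared_blocks <- function(genomes) {
  blocks <- genomes[[1L]]$blocks
  for (g in genomes) {
    if (!identical(g$blocks, blocks)) {
      abort(sprintf("genome %s has a different block set.", g$name))
    }
  }
  blocks
}

#' Build the conflict graph of a genome collection
#'
#' Vertices are the extremities occurring in the genomes; edges are the
#' adjacencies present in exactly half of the genomes (empty for an odd
#' number of genomes). Adjacencies present in more than half form the
#' majority set, which is always conflict-free.
#'
#' @param genomes List of `scj_genome`s over one block set, or an adjacency
#'   data frame (`genome`, `extremity1`, `extremity2`).
#' @return An `scj_conflict_graph`: list with `counts` (tibble `adjacency`,
#'   `count`), `n_genomes`, `majority` (adjacency keys), `half` (keys on
#'   edges), `vertices` (extremities) and `degree` (named integer vector).
#' @export
conflict_graph <- function(genomes) {
  genomes <- as_genome_list(genomes)
  check_shared_blocks(genomes)
  k <- length(genomes)
  all_adj <- unlist(lapply(genomes, function(g) g$adjacencies), use.names = FALSE)
  counts <- table(all_adj)
  keys <- names(counts)
  cnt <- as.integer(counts)
  majority <- keys[cnt * 2L > k]
  half <- keys[cnt * 2L == k]
  vertices <- sort(unique(as.vector(adj_ends(keys))), method = "radix")
  deg <- stats::setNames(rep(0L, length(vertices)), vertices)
  he <- adj_ends(half)
  for (e in as.vector(he)) {
    deg[e] <- deg[e] + 1L
  }
  if (any(deg > 2L)) {
    abort("conflict-graph degree exceeds 2; this contradicts half-frequency counting.")
  }
  structure(
    list(
      counts = tibble(adjacency = keys, count = cnt),
      n_genomes = k, majority = majority, half = half,
      vertices = vertices, degree = deg
    ),
    class = "scj_conflict_graph"
  )
}

#' @export
print.scj_conflict_graph <- function(x, ...) {
  cat(sprintf("<scj_conflict_graph> %d extremities, %d half-frequency edges, %d majority adjacencies\n",
              length(x$vertices), length(x$half), length(x$majority)))
  invisible(x)
}

# Ordered decomposition of the half-frequency edges into paths and cycles.
# Returns a list of components: list(kind, edges = ordered adjacency keys).
component_walks <- function(cg) {
  half <- cg$half
  ends <- adj_ends(half)
  n <- length(half)
  # incidence: extremity -> indices of half edges touching it
  inc <- split(rep(seq_len(n), 2L), c(ends[, 1L], ends[, 2L]))
  used <- logical(n)
  comps <- list()

  walk_from <- function(start_ext) {
    ord <- integer(0)
    ext <- start_ext
    repeat {
      cand <- inc[[ext]]
      cand <- cand[!used[cand]]
      if (is.null(cand) || length(cand) == 0L) {
        return(ord)
      }
      e <- cand[1L]
      used[e] <<- TRUE
      ord <- c(ord, e)
      pair <- ends[e, ]
      ext <- if (pair[1L] == ext) pair[2L] else pair[1L]
    }
  }

  deg <- cg$degree
  # paths first: start at degree-1 extremities (deterministic order)
  for (startx in names(deg)[deg == 1L]) {
    cand <- inc[[startx]]
    if (all(used[cand])) next
    ord <- walk_from(startx)
    comps[[length(comps) + 1L]] <- list(kind = "path", edges = half[ord])
  }
  # remaining edges form cycles
  for (e0 in seq_len(n)) {
    if (used[e0]) next
    ord <- walk_from(ends[e0, 1L])
    comps[[length(comps) + 1L]] <- list(kind = "cycle", edges = half[ord])
  }
  comps
}

#' Decompose the conflict graph into isolated vertices, paths and cycles
#'
#' @param cg An `scj_conflict_graph`.
#' @return Tibble with one row per connected component: `component`, `kind`
#'   (`"isolated"`, `"path"` or `"cycle"`) and `n_edges`.
#' @export
decompose_conflict_graph <- function(cg) {
  comps <- component_walks(cg)
  n_iso <- sum(!cg$vertices %in% as.vector(adj_ends(cg$half)))
  kinds <- c(rep("isolated", n_iso), vapply(comps, `[[`, character(1), "kind"))
  sizes <- c(rep(0L, n_iso), vapply(comps, function(cp) length(cp$edges), integer(1)))
  tibble(component = seq_along(kinds), kind = kinds, n_edges = sizes)
}

#' Count matchings of a path or cycle
#'
#' Counts edge subsets with no shared vertex, including the empty matching.
#' On a path with `n` edges the count follows `M(n) = M(n-1) + M(n-2)` with
#' `M(0) = 1`, `M(1) = 2` (shifted Fibonacci numbers); on a cycle with `n`
#' edges it is the `n`-th Lucas number.
#'
#' @param n_edges Number of edges (path: >= 0; cycle: >= 3).
#' @return Count as a double (exact for counts below 2^53).
#' @export
count_matchings_path <- function(n_edges) {
  stopifnot(length(n_edges) == 1L, n_edges >= 0L)
  a <- 1  # M(0)
  b <- 2  # M(1)
  if (n_edges == 0L) return(a)
  for (j in seq_len(n_edges - 1L)) {
    tmp <- a + b
    a <- b
    b <- tmp
  }
  b
}

#' @rdname count_matchings_path
#' @export
count_matchings_cycle <- function(n_edges) {
  stopifnot(length(n_edges) == 1L, n_edges >= 3L)
  # Lucas: L(n) = matchings of the n-cycle = M_path(n-1) + M_path(n-3)
  count_matchings_path(n_edges - 1L) + count_matchings_path(n_edges - 3L)
}

#' Count the optimal SCJ medians of a genome collection
#'
#' Product over conflict-graph components of the per-component matching
#' counts; 1 whenever the conflict graph has no edges — in particular for
#' any odd number of genomes, whose optimal median (the majority genome) is
#' unique.
#'
#' @inheritParams conflict_graph
#' @return Count as a double (exact below 2^53).
#' @export
count_scj_medians <- function(genomes) {
  cg <- conflict_graph(as_genome_list(genomes))
  comps <- component_walks(cg)
  prod(vapply(comps, function(cp) {
    if (cp$kind == "path") count_matchings_path(length(cp$edges))
    else count_matchings_cycle(length(cp$edges))
  }, numeric(1)))
}

#' The majority median
#'
#' The genome made of the adjacencies present in more than half of the
#' genomes. Always a valid genome (two conflicting adjacencies cannot both
#' be in a strict majority), always an optimal median, and the unique
#' optimal median when the number of genomes is odd.
#'
#' @inheritParams conflict_graph
#' @param name Name for the output genome.
#' @return An `scj_genome`.
#' @export
majority_median <- function(genomes, name = "median") {
  genomes <- as_genome_list(genomes)
  blocks <- check_shared_blocks(genomes)
  cg <- conflict_graph(genomes)
  genome(name, blocks, cg$majority)
}

# all matchings of an ordered path, as a list of integer index vectors
# (indices into the component's edge order)
path_matchings <- function(n) {
  if (n == 0L) return(list(integer(0)))
  if (n == 1L) return(list(integer(0), 1L))
  without <- path_matchings(n - 1L)
  with <- lapply(path_matchings(n - 2L), function(mm) c(mm, n))
  c(without, with)
}

cycle_matchings <- function(n) {
  # condition on edge 1: excluded -> any matching of path 2..n;
  # included -> edges 2 and n excluded, any matching of path 3..(n-1)
  without <- lapply(path_matchings(n - 1L), function(mm) mm + 1L)
  with <- lapply(path_matchings(n - 3L), function(mm) c(1L, mm + 2L))
  c(without, with)
}

#' Enumerate all optimal SCJ medians
#'
#' @inheritParams conflict_graph
#' @param cap Refuse enumeration when the median count exceeds `cap`.
#' @return Named list of `scj_genome`s (`median1`, `median2`, ...), one per
#'   optimal median; each is the majority set plus one matching of the
#'   conflict graph.
#' @export
enumerate_scj_medians <- function(genomes, cap = 10000) {
  genomes <- as_genome_list(genomes)
  blocks <- check_shared_blocks(genomes)
  n_med <- count_scj_medians(genomes)
  if (n_med > cap) {
    abort(sprintf("median count %.0f exceeds cap %.0f.", n_med, cap))
  }
  cg <- conflict_graph(genomes)
  comps <- component_walks(cg)
  per_comp <- lapply(comps, function(cp) {
    n <- length(cp$edges)
    ms <- if (cp$kind == "path") path_matchings(n) else cycle_matchings(n)
    lapply(ms, function(mm) cp$edges[mm])
  })
  combos <- list(character(0))
  for (pc in per_comp) {
    combos <- unlist(
      lapply(combos, function(base) lapply(pc, function(sel) c(base, sel))),
      recursive = FALSE
    )
  }
  out <- lapply(seq_along(combos), function(j) {
    genome(paste0("median", j), blocks, c(cg$majority, combos[[j]]))
  })
  stopifnot(length(out) == n_med)
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}

# uniform matching of an ordered path by backward simulation of the
# recurrence; returns indices of included edges
sample_path_matching <- function(n) {
  sel <- integer(0)
  j <- 1L
  while (j <= n) {
    rest_with <- if (j + 2L <= n) count_matchings_path(n - j - 1L) else 1
    rest_without <- if (j + 1L <= n) count_matchings_path(n - j) else 1
    if (stats::runif(1) * (rest_with + rest_without) < rest_with) {
      sel <- c(sel, j)
      j <- j + 2L
    } else {
      j <- j + 1L
    }
  }
  sel
}

#' Draw a uniform optimal SCJ median
#'
#' For an odd number of genomes this is deterministic and equals
#' [majority_median()]. For an even number, one matching is drawn uniformly
#' per conflict-graph component by backward simulation of the matching
#' recurrence, and unioned with the majority set. Uses the current RNG
#' state; seed with [set.seed()] for reproducibility.
#'
#' @inheritParams majority_median
#' @return An `scj_genome` whose total SCJ distance to the inputs is minimal.
#' @export
sample_scj_median <- function(genomes, name = "median") {
  genomes <- as_genome_list(genomes)
  blocks <- check_shared_blocks(genomes)
  cg <- conflict_graph(genomes)
  comps <- component_walks(cg)
  picked <- character(0)
  for (cp in comps) {
    n <- length(cp$edges)
    if (cp$kind == "path") {
      sel <- sample_path_matching(n)
    } else {
      w_with <- count_matchings_path(n - 3L)   # edge 1 in the matching
      w_without <- count_matchings_path(n - 1L)
      if (stats::runif(1) * (w_with + w_without) < w_with) {
        sel <- c(1L, sample_path_matching(n - 3L) + 2L)
      } else {
        sel <- sample_path_matching(n - 1L) + 1L
      }
    }
    picked <- c(picked, cp$edges[sel])
  }
  genome(name, blocks, c(cg$majority, picked))
}
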