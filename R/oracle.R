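# Brute-force reference implementations. These define ground truth on tiny
# instances for the polynomial-time machinery and the sampler; they refuse
# (rather than truncate) instances above their caps.

#' Enumerate all valid 0-1 vectors over a universe
#'
#' All conflict-free subsets of the universe's adjacencies, as 0-1 vectors,
#' ordered by their binary encoding (coordinate 1 = lowest bit). The search
#' recurses coordinate by coordinate and prunes conflicting branches, so its
#' cost is proportional to the number of valid vectors, not 2^|A|.
#'
#' @param universe An `scj_universe`.
#' @param cap Maximum universe size (default 20; the count of valid vectors,
#'   not the cap, drives the run time).
#' @return List of integer 0/1 vectors.
#' @export
enumerate_valid_vectors <- function(universe, cap = 20L) {
  n <- length(universe$keys)
  if (n > cap) {
    abort(sprintf("universe size %d exceeds enumeration cap %d.", n, cap))
  }
  if (n == 0L) {
    return(list(integer(0)))
  }
  out <- vector("list", 256L)
  n_out <- 0L
  emit <- function(bits) {
    n_out <<- n_out + 1L
    if (n_out > length(out)) length(out) <<- 2L * n_out
    out[[n_out]] <<- bits
  }
  conflicts <- universe$conflicts
  bits <- integer(n)
  # coordinate `pos` counts down so that coordinate 1 varies fastest,
  # matching the binary-encoding order
  recurse <- function(pos) {
    if (pos == 0L) {
      emit(bits)
      return(invisible())
    }
    bits[pos] <<- 0L
    recurse(pos - 1L)
    if (!any(bits[conflicts[[pos]]] == 1L)) {
      bits[pos] <<- 1L
      recurse(pos - 1L)
      bits[pos] <<- 0L
    }
    invisible()
  }
  recurse(n)
  out[seq_len(n_out)]
}

#' Exhaustively enumerate all most parsimonious valid labelings
#'
#' Assigns every combination of valid vectors to the internal nodes, scores
#' each, and returns all minimizers — the ground-truth solution set the
#' Gibbs sampler targets.
#'
#' @param instance An `scj_instance`.
#' @param cap Maximum number of combinations (default 2e6).
#' @return List with `score` (the optimum) and `labelings` (list of full
#'   labeling matrices, deterministically ordered).
#' @export
enumerate_optimal_labelings <- function(instance, cap = 2e6) {
  tree <- instance$tree
  vecs <- enumerate_valid_vectors(instance$universe)
  n_int <- tree$n_vertex - tree$n_tip
  n_comb <- length(vecs)^n_int
  if (n_comb > cap) {
    abort(sprintf("%.0f combinations exceed enumeration cap %.0f.", n_comb, cap))
  }
  # vectorized scoring: pairwise Hamming distances between valid vectors,
  # then one lookup per edge per combination
  vm <- do.call(rbind, vecs)
  nvec <- nrow(vm)
  D <- as.matrix(stats::dist(vm, method = "manhattan"))
  combos <- as.matrix(expand.grid(rep(list(seq_len(nvec)), n_int)))
  nt <- tree$n_tip
  score <- numeric(nrow(combos))
  for (r in seq_len(nrow(tree$edges))) {
    p <- tree$edges[r, 1L]
    v <- tree$edges[r, 2L]
    if (v <= nt) {
      dl <- rowSums(abs(vm - matrix(instance$leaf_matrix[v, ], nvec,
                                    ncol(vm), byrow = TRUE)))
      score <- score + dl[combos[, p - nt]]
    } else {
      score <- score + D[cbind(combos[, p - nt], combos[, v - nt])]
    }
  }
  best <- min(score)
  hits <- which(score == best)
  out <- lapply(hits, function(h) {
    new_labeling(instance, vm[combos[h, ], , drop = FALSE])
  })
  list(score = as.integer(best), labelings = out)
}

#' Enumerate the Gibbs conditional support for one coordinate
#'
#' All assignments of coordinate `i` to the internal vertices that keep
#' every vertex's genome valid and keep the total score at the global
#' optimum, holding every other coordinate of `labeling` fixed. This is the
#' set [resample_coordinate()] must draw from uniformly.
#'
#' @param instance An `scj_instance`.
#' @param labeling A most parsimonious valid labeling.
#' @param i Coordinate index.
#' @return List of integer 0/1 vectors over the internal vertices (in vertex
#'   order), deterministically ordered.
#' @export
enumerate_compatible <- function(instance, labeling, i) {
  tree <- instance$tree
  internal <- (tree$n_tip + 1L):tree$n_vertex
  n_int <- length(internal)
  score <- tree_score(instance, labeling)
  out <- list()
  for (code in 0:(2^n_int - 1)) {
    bits <- as.integer(bitwAnd(bitwShiftR(code, 0:(n_int - 1)), 1L))
    cand <- labeling
    cand[internal, i] <- bits
    if (tree_score(instance, cand) != score) next
    ok <- all(vapply(internal, function(v) is_valid_vector(cand[v, ], instance$universe),
                     logical(1)))
    if (ok) {
      out[[length(out) + 1L]] <- bits
    }
  }
  out
}

#' Count matchings of an arbitrary graph by brute force
#'
#' @param edges Two-column matrix (or data frame) of vertex labels, one row
#'   per edge.
#' @param cap Maximum number of edges (default 20).
#' @return Number of edge subsets with no shared vertex, including the
#'   empty one.
#' @export
count_matchings_bruteforce <- function(edges, cap = 20L) {
  edges <- as.matrix(edges)
  n <- nrow(edges)
  if (n > cap) {
    abort(sprintf("%d edges exceed brute-force cap %d.", n, cap))
  }
  if (n == 0L) {
    return(1)
  }
  count <- 0
  for (code in 0:(2^n - 1)) {
    sel <- which(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L) == 1L)
    verts <- as.vector(edges[sel, , drop = FALSE])
    if (anyDuplicated(verts) == 0L) {
      count <- count + 1
    }
  }
  count
}

#' Brute-force optimal SCJ medians
#'
#' Enumerates every conflict-free subset of the adjacencies observed in the
#' input genomes, computes its total SCJ distance to the inputs, and
#' returns all minimizers. Restricting the search to observed adjacencies
#' loses no optimum: an adjacency absent from every input adds its own
#' multiplicity to the objective and can always be dropped.
#'
#' @inheritParams conflict_graph
#' @param cap Maximum number of distinct observed adjacencies (default 26).
#' @return List with `score` (minimal total distance) and `medians` (list of
#'   `scj_genome`s).
#' @export
bruteforce_medians <- function(genomes, cap = 26L) {
  genomes <- as_genome_list(genomes)
  blocks <- check_shared_blocks(genomes)
  universe <- adjacency_universe(genomes)
  vecs <- enumerate_valid_vectors(universe, cap = cap)
  enc <- lapply(genomes, encode_genome, universe = universe)
  best <- Inf
  out <- list()
  for (bits in vecs) {
    tot <- sum(vapply(enc, function(x) sum(abs(x - bits)), numeric(1)))
    if (tot < best) {
      best <- tot
      out <- list(bits)
    } else if (tot == best) {
      out[[length(out) + 1L]] <- bits
    }
  }
  medians <- lapply(seq_along(out), function(j) {
    decode_genome(out[[j]], universe, blocks, name = paste0("median", j))
  })
  list(score = best, medians = medians)
}
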