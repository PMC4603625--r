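# Per-adjacency small parsimony on the 0/1 (absent/present) alphabet.
#
# Fitch sets B(v) are encoded as integers: 1 = {0}, 2 = {1}, 3 = {0,1};
# intersection is bitwAnd, union bitwOr. Sankoff costs use an integer
# sentinel INF with saturating addition: attainable costs are bounded by the
# number of tree edges, so the sentinel never wraps.

INF <- 1000000000L

sat_add1 <- function(x) ifelse(x >= INF, INF, x + 1L)

#' Fitch bottom-up phase for one 0/1 character
#'
#' @param tree An `scj_tree`.
#' @param leaf_chars Integer 0/1 vector, one character per leaf (leaf order).
#' @return Integer vector of length `n_vertex` coding the candidate set
#'   `B(v)`: 1 = \{0\}, 2 = \{1\}, 3 = \{0,1\}.
#' @details Each internal node takes the intersection of its children's sets
#'   when nonempty, else their union.
#' @export
fitch_bottom_up <- function(tree, leaf_chars) {
  stopifnot(length(leaf_chars) == tree$n_tip, all(leaf_chars %in% 0:1))
  B <- integer(tree$n_vertex)
  B[seq_len(tree$n_tip)] <- ifelse(leaf_chars == 1L, 2L, 1L)
  for (v in tree$postorder) {
    if (v <= tree$n_tip) next
    b1 <- B[tree$children[v, 1L]]
    b2 <- B[tree$children[v, 2L]]
    inter <- bitwAnd(b1, b2)
    B[v] <- if (inter != 0L) inter else bitwOr(b1, b2)
  }
  B
}

#' Fitch top-down phase with absence preferred at the root
#'
#' Assigns a character to every vertex from the bottom-up sets: the root
#' takes 0 whenever `B(root) = {0,1}` (the canonical tie-break that keeps
#' genome labelings valid), and each child copies its parent's character when
#' that character is in its set, else takes the single member of its set.
#' On the 0/1 alphabet this is unambiguous below the root.
#'
#' @param tree An `scj_tree`.
#' @param B Codes from [fitch_bottom_up()].
#' @return Integer 0/1 vector over all vertices.
#' @export
fitch_top_down <- function(tree, B) {
  f <- integer(tree$n_vertex)
  for (v in tree$preorder) {
    if (v == tree$root) {
      f[v] <- if (bitwAnd(B[v], 1L) != 0L) 0L else 1L
    } else {
      p <- f[tree$parent[v]]
      pcode <- bitwShiftL(1L, p)
      f[v] <- if (bitwAnd(B[v], pcode) != 0L) p else (if (B[v] == 1L) 0L else 1L)
    }
  }
  f
}

#' Sankoff-Rousseau costs for one 0/1 character
#'
#' Dynamic program over the tree: `s(v,k)` is the minimum number of character
#' changes in the subtree below `v` given character `k` at `v`. Leaves score
#' 0 for their observed character and infinity otherwise; an internal node
#' adds, for each child, the cheaper of keeping or flipping the character.
#'
#' @param tree An `scj_tree`.
#' @param leaf_chars Integer 0/1 vector over leaves.
#' @return `n_vertex` x 2 integer matrix, columns `s0`, `s1`; the sentinel
#'   `1e9` stands for infinity.
#' @export
sankoff <- function(tree, leaf_chars) {
  stopifnot(length(leaf_chars) == tree$n_tip, all(leaf_chars %in% 0:1))
  s <- matrix(INF, nrow = tree$n_vertex, ncol = 2L,
              dimnames = list(tree$labels, c("s0", "s1")))
  s[cbind(seq_len(tree$n_tip), leaf_chars + 1L)] <- 0L
  for (v in tree$postorder) {
    if (v <= tree$n_tip) next
    u1 <- tree$children[v, 1L]
    u2 <- tree$children[v, 2L]
    s[v, 1L] <- pmin(s[u1, 1L], sat_add1(s[u1, 2L])) +
      pmin(s[u2, 1L], sat_add1(s[u2, 2L]))
    s[v, 2L] <- pmin(sat_add1(s[u1, 1L]), s[u1, 2L]) +
      pmin(sat_add1(s[u2, 1L]), s[u2, 2L])
  }
  s
}

#' Per-character parsimony optimum
#'
#' @param s Cost matrix from [sankoff()].
#' @param tree The `scj_tree` the table was computed on.
#' @return `min(s(root, 0), s(root, 1))`.
#' @export
coordinate_min <- function(s, tree) {
  min(s[tree$root, ])
}

# all-coordinate Fitch codes: n_vertex x |A| matrix of set codes
fitch_codes <- function(instance) {
  tree <- instance$tree
  nA <- ncol(instance$leaf_matrix)
  B <- matrix(0L, nrow = tree$n_vertex, ncol = nA)
  B[seq_len(tree$n_tip), ] <- ifelse(instance$leaf_matrix == 1L, 2L, 1L)
  for (v in tree$postorder) {
    if (v <= tree$n_tip) next
    b1 <- B[tree$children[v, 1L], ]
    b2 <- B[tree$children[v, 2L], ]
    inter <- bitwAnd(b1, b2)
    B[v, ] <- ifelse(inter != 0L, inter, bitwOr(b1, b2))
  }
  rownames(B) <- tree$labels
  B
}

# all-coordinate Sankoff: list(s0, s1), each n_vertex x |A|
sankoff_all <- function(instance) {
  tree <- instance$tree
  nA <- ncol(instance$leaf_matrix)
  s0 <- matrix(INF, nrow = tree$n_vertex, ncol = nA)
  s1 <- matrix(INF, nrow = tree$n_vertex, ncol = nA)
  lt <- seq_len(tree$n_tip)
  s0[lt, ][instance$leaf_matrix == 0L] <- 0L
  s1[lt, ][instance$leaf_matrix == 1L] <- 0L
  for (v in tree$postorder) {
    if (v <= tree$n_tip) next
    u1 <- tree$children[v, 1L]
    u2 <- tree$children[v, 2L]
    s0[v, ] <- pmin(s0[u1, ], sat_add1(s1[u1, ])) + pmin(s0[u2, ], sat_add1(s1[u2, ]))
    s1[v, ] <- pmin(sat_add1(s0[u1, ]), s1[u1, ]) + pmin(sat_add1(s0[u2, ]), s1[u2, ])
  }
  list(s0 = s0, s1 = s1)
}

#' Canonical most parsimonious labeling
#'
#' Applies the Fitch algorithm independently to every adjacency coordinate,
#' choosing absence (0) at the root whenever both states tie. The resulting
#' vectors are always conflict-free, so this is a most parsimonious *valid*
#' labeling, attaining the sum over coordinates of the per-coordinate optima.
#'
#' @param instance An `scj_instance` from [bind_genomes()].
#' @return `n_vertex` x |A| 0-1 matrix (rows named by vertex labels).
#' @export
canonical_labeling <- function(instance) {
  tree <- instance$tree
  B <- fitch_codes(instance)
  nA <- ncol(B)
  f <- matrix(0L, nrow = tree$n_vertex, ncol = nA)
  for (v in tree$preorder) {
    if (v == tree$root) {
      f[v, ] <- ifelse(bitwAnd(B[v, ], 1L) != 0L, 0L, 1L)
    } else {
      p <- f[tree$parent[v], ]
      pcode <- bitwShiftL(1L, p)
      f[v, ] <- ifelse(bitwAnd(B[v, ], pcode) != 0L, p, ifelse(B[v, ] == 1L, 0L, 1L))
    }
  }
  lab <- new_labeling(instance, f[-(seq_len(tree$n_tip)), , drop = FALSE])
  stopifnot(all(lab[seq_len(tree$n_tip), ] == f[seq_len(tree$n_tip), ]))
  lab
}

#' Tabulate Fitch sets and Sankoff costs per coordinate
#'
#' A long-format diagnostic dump of the two dynamic programs, one row per
#' (vertex, adjacency) pair; useful for inspecting small instances.
#'
#' @param instance An `scj_instance`.
#' @return Tibble with columns `vertex`, `adjacency`, `B` (the candidate set
#'   as `"0"`, `"1"` or `"01"`), `s0`, `s1` (`NA` for infinity).
#' @export
fitch_table <- function(instance) {
  B <- fitch_codes(instance)
  s <- sankoff_all(instance)
  nA <- ncol(B)
  nv <- instance$tree$n_vertex
  dena <- function(x) ifelse(x >= INF, NA_integer_, x)
  tibble(
    vertex = rep(instance$tree$labels, times = nA),
    adjacency = rep(instance$universe$keys, each = nv),
    B = c("0", "1", "01")[as.vector(B)],
    s0 = dena(as.vector(s$s0)),
    s1 = dena(as.vector(s$s1))
  )
}
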