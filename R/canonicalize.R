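# Canonicalization: transforms any most parsimonious valid labeling into the
# canonical Fitch labeling by a finite sequence of single-coordinate moves,
# each itself an admissible Gibbs step (valid and score-preserving). This is
# the constructive irreducibility argument for the sampler, executed and
# asserted rather than just stated.
#
# Three phases over the per-adjacency Fitch sets B:
#  1. while some (vertex v, adjacency a) of minimal height has B_a(v) = {0}
#     but a present at v: remove a at v and re-propagate a below v by Fitch
#     as if v were the root;
#  2. symmetrically, B_a(v) = {1} with a absent: add and re-propagate;
#  3. for each adjacency a whose root component C (maximal connected vertex
#     set containing the root with B_a = {0,1} throughout) carries a
#     somewhere: set a absent across C.
# The result must equal the canonical labeling; every intermediate labeling
# is checked valid and score-preserving.

vertex_heights <- function(tree) {
  h <- integer(tree$n_vertex)
  for (v in tree$postorder) {
    if (v > tree$n_tip) {
      h[v] <- 1L + max(h[tree$children[v, ]])
    }
  }
  h
}

subtree_preorder <- function(tree, v) {
  out <- integer(0)
  stack <- v
  while (length(stack) > 0L) {
    w <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, w)
    if (w > tree$n_tip) {
      stack <- c(stack, tree$children[w, 2L], tree$children[w, 1L])
    }
  }
  out
}

# Fitch top-down re-propagation of coordinate codes below v, with character
# k forced at v; returns updated column of 0/1 chars
propagate_below <- function(tree, Bcol, chars, v, k) {
  chars[v] <- k
  for (w in subtree_preorder(tree, v)) {
    if (w == v) next
    p <- chars[tree$parent[w]]
    pcode <- bitwShiftL(1L, p)
    chars[w] <- if (bitwAnd(Bcol[w], pcode) != 0L) p else (if (Bcol[w] == 1L) 0L else 1L)
  }
  chars
}

# maximal connected vertex set containing the root with code == 3 throughout
root_component <- function(tree, Bcol) {
  if (Bcol[tree$root] != 3L) {
    return(integer(0))
  }
  comp <- integer(0)
  stack <- tree$root
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    comp <- c(comp, v)
    if (v > tree$n_tip) {
      for (u in tree$children[v, ]) {
        if (Bcol[u] == 3L) stack <- c(stack, u)
      }
    }
  }
  comp
}

#' Canonicalize a most parsimonious labeling by Gibbs moves
#'
#' Executes the constructive irreducibility procedure: a finite sequence of
#' single-coordinate moves, each valid and score-preserving, taking `labeling`
#' to the canonical Fitch labeling. Errors if any intermediate labeling
#' violates validity or changes the score, or if the final labeling is not
#' canonical — any of these would indicate a bug, since the construction
#' guarantees success for genuinely most parsimonious valid inputs.
#'
#' @param instance An `scj_instance`.
#' @param labeling A most parsimonious valid labeling matrix.
#' @return List with `moves` (tibble: `phase`, `vertex`, `adjacency`,
#'   `action`), `labelings` (list of intermediate labelings after each move)
#'   and `final` (the canonical labeling).
#' @export
canonicalize_labeling <- function(instance, labeling) {
  tree <- instance$tree
  score <- tree_score(instance, labeling)
  B <- fitch_codes(instance)
  h <- vertex_heights(tree)
  keys <- instance$universe$keys
  moves <- list()
  labelings <- list()

  check <- function(lab) {
    if (tree_score(instance, lab) != score) {
      abort("canonicalization move changed the parsimony score; this is a bug.")
    }
    if (!labeling_is_valid(instance, lab)) {
      abort("canonicalization move produced an invalid genome; this is a bug.")
    }
    lab
  }
  log_move <- function(phase, v, i, action, lab) {
    moves[[length(moves) + 1L]] <<- tibble(
      phase = phase, vertex = tree$labels[v], adjacency = keys[i], action = action
    )
    labelings[[length(labelings) + 1L]] <<- lab
  }

  guard <- tree$n_vertex * max(1L, length(keys)) * 4L + 16L
  for (phase in 1:2) {
    want_code <- if (phase == 1L) 1L else 2L    # B = {0} / B = {1}
    bad_state <- if (phase == 1L) 1L else 0L    # present / absent
    repeat {
      guard <- guard - 1L
      if (guard < 0L) abort("canonicalization failed to terminate; this is a bug.")
      viol <- which(B == want_code & labeling == bad_state, arr.ind = TRUE)
      if (nrow(viol) == 0L) break
      pick <- viol[order(h[viol[, 1L]], viol[, 1L], viol[, 2L])[1L], ]
      v <- pick[[1L]]
      i <- pick[[2L]]
      labeling[, i] <- propagate_below(tree, B[, i], labeling[, i], v, 1L - bad_state)
      labeling <- check(labeling)
      log_move(phase, v, i,
               if (phase == 1L) "remove-and-propagate" else "add-and-propagate",
               labeling)
    }
  }

  for (i in seq_along(keys)) {
    comp <- root_component(tree, B[, i])
    if (length(comp) > 0L && any(labeling[comp, i] == 1L)) {
      labeling[comp, i] <- 0L
      labeling <- check(labeling)
      log_move(3L, tree$root, i, "clear-root-component", labeling)
    }
  }

  canon <- canonical_labeling(instance)
  if (!identical(unname(labeling), unname(canon))) {
    abort("canonicalization did not reach the canonical labeling; this is a bug.")
  }
  moves_df <- if (length(moves) > 0L) {
    do.call(rbind, moves)
  } else {
    tibble(phase = integer(), vertex = character(),
           adjacency = character(), action = character())
  }
  list(moves = moves_df, labelings = labelings, final = labeling)
}
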