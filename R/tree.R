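# Rooted strictly binary trees. ape does the Newick parsing; on top of it we
# enforce binarity, name internal nodes, and precompute the traversal orders
# and child/parent maps the per-adjacency dynamic programs need.
#
# Vertex indexing follows ape: leaves 1..n_tip, internal n_tip+1..2*n_tip-1,
# root = n_tip + 1.

#' Parse a rooted binary tree from Newick
#'
#' @param text Newick string, or `NULL` to read from `file`.
#' @param file Path to a Newick file.
#' @return An `scj_tree`: list with `n_tip`, `n_vertex`, `labels` (length
#'   `n_vertex`; unlabeled internal nodes are auto-named `N1..Nk` in
#'   preorder), `root`, `parent` (NA at the root), `children`
#'   (`n_vertex` x 2, NA rows for leaves), `postorder`/`preorder` vertex
#'   orders, and `edges` (parent, child; one row per tree edge, preorder of
#'   the child).
#' @details Branch lengths are ignored. Multifurcations (including a
#'   trifurcating root), unary internal nodes, duplicate or missing leaf
#'   names are rejected, naming the offending node.
#' @export
read_tree_newick <- function(text = NULL, file = NULL) {
  phy <- tryCatch(
    suppressWarnings(
      if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file = file)
    ),
    error = function(e) abort(sprintf("Newick parse failed: %s", conditionMessage(e)))
  )
  if (is.null(phy)) {
    abort("Newick parse failed: no tree found in input.")
  }
  n_tip <- length(phy$tip.label)
  if (n_tip < 2L) {
    abort("tree must have at least 2 leaves.")
  }
  if (anyDuplicated(phy$tip.label) > 0L) {
    dup <- phy$tip.label[duplicated(phy$tip.label)][1L]
    abort(sprintf("duplicate leaf name: %s.", dup))
  }
  if (any(phy$tip.label == "")) {
    abort(sprintf("unnamed leaf (tip number %d).", which(phy$tip.label == "")[1L]))
  }
  n_vertex <- n_tip + phy$Nnode
  deg <- tabulate(phy$edge[, 1L], nbins = n_vertex)
  internal <- (n_tip + 1L):n_vertex
  bad <- internal[deg[internal] != 2L]
  if (length(bad) > 0L) {
    v <- bad[1L]
    what <- if (deg[v] > 2L) "multifurcation" else "unary internal node"
    abort(sprintf("tree is not strictly binary: %s at internal node %d (%d children).",
                  what, v, deg[v]))
  }

  parent <- rep(NA_integer_, n_vertex)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- which(is.na(parent) & seq_len(n_vertex) > n_tip)
  children <- matrix(NA_integer_, nrow = n_vertex, ncol = 2L)
  for (r in seq_len(nrow(phy$edge))) {
    v <- phy$edge[r, 1L]
    children[v, if (is.na(children[v, 1L])) 1L else 2L] <- phy$edge[r, 2L]
  }

  # iterative preorder / postorder
  preorder <- integer(0)
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    preorder <- c(preorder, v)
    if (v > n_tip) {
      stack <- c(stack, children[v, 2L], children[v, 1L])
    }
  }
  postorder <- rev(preorder)  # children precede parents (right-left preorder reversed)

  labels <- c(phy$tip.label, rep(NA_character_, phy$Nnode))
  if (!is.null(phy$node.label)) {
    nl <- phy$node.label
    nl[nl == ""] <- NA_character_
    labels[(n_tip + 1L):n_vertex] <- nl
  }
  auto <- 0L
  for (v in preorder) {
    if (v > n_tip && is.na(labels[v])) {
      repeat {
        auto <- auto + 1L
        cand <- paste0("N", auto)
        if (!cand %in% labels) break
      }
      labels[v] <- cand
    }
  }
  if (anyDuplicated(labels) > 0L) {
    abort(sprintf("duplicate node label: %s.", labels[duplicated(labels)][1L]))
  }

  child_pre <- preorder[preorder != root]
  edges <- cbind(parent = parent[child_pre], child = child_pre)
  structure(
    list(
      n_tip = n_tip, n_vertex = n_vertex, labels = labels, root = root,
      parent = parent, children = children,
      preorder = preorder, postorder = postorder, edges = edges
    ),
    class = "scj_tree"
  )
}

#' @export
print.scj_tree <- function(x, ...) {
  cat(sprintf("<scj_tree> %d leaves, %d internal nodes\n", x$n_tip, x$n_vertex - x$n_tip))
  cat("  leaves:", paste(x$labels[seq_len(x$n_tip)], collapse = ", "), "\n")
  invisible(x)
}

edge_names <- function(tree) {
  paste0(tree$labels[tree$edges[, 1L]], "->", tree$labels[tree$edges[, 2L]])
}

#' Bind leaf genomes to a tree
#'
#' Attaches a genome to every leaf and derives the adjacency universe (the
#' distinct adjacencies over all leaves, first-seen in leaf order) and the
#' leaf 0-1 matrix the per-adjacency dynamic programs run on.
#'
#' @param tree An `scj_tree`.
#' @param genomes Named list of `scj_genome`s; names must match the leaf
#'   labels exactly, and all genomes must share one block set.
#' @return An `scj_instance`: list with `tree`, `genomes` (leaf order),
#'   `blocks`, `universe` and `leaf_matrix` (`n_tip` x |A| 0-1, rows in leaf
#'   order).
#' @export
bind_genomes <- function(tree, genomes) {
  stopifnot(inherits(tree, "scj_tree"))
  leaves <- tree$labels[seq_len(tree$n_tip)]
  missing <- setdiff(leaves, names(genomes))
  if (length(missing) > 0L) {
    abort(sprintf("no genome for leaf: %s.", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(genomes), leaves)
  if (length(extra) > 0L) {
    abort(sprintf("genome name matches no leaf: %s.", paste(extra, collapse = ", ")))
  }
  genomes <- genomes[leaves]
  blocks <- genomes[[1L]]$blocks
  for (g in genomes) {
    if (!identical(g$blocks, blocks)) {
      abort(sprintf("genome %s has a different block set.", g$name))
    }
  }
  universe <- adjacency_universe(genomes)
  leaf_matrix <- do.call(rbind, lapply(genomes, encode_genome, universe = universe))
  if (is.null(leaf_matrix)) {
    leaf_matrix <- matrix(0L, nrow = tree$n_tip, ncol = 0L)
  }
  rownames(leaf_matrix) <- leaves
  structure(
    list(tree = tree, genomes = genomes, blocks = blocks,
         universe = universe, leaf_matrix = leaf_matrix),
    class = "scj_instance"
  )
}

#' @export
print.scj_instance <- function(x, ...) {
  cat(sprintf("<scj_instance> %d leaves, %d blocks, %d adjacencies in universe\n",
              x$tree$n_tip, length(x$blocks), length(x$universe$keys)))
  invisible(x)
}

# full labeling: n_vertex x |A| 0-1 integer matrix, leaf rows equal to
# leaf_matrix, rownames = tree labels
new_labeling <- function(instance, internal_bits) {
  nv <- instance$tree$n_vertex
  nt <- instance$tree$n_tip
  lab <- matrix(0L, nrow = nv, ncol = ncol(instance$leaf_matrix))
  lab[seq_len(nt), ] <- instance$leaf_matrix
  if (nv > nt) lab[(nt + 1L):nv, ] <- internal_bits
  rownames(lab) <- instance$tree$labels
  lab
}

labeling_is_valid <- function(instance, labeling) {
  all(vapply(seq_len(nrow(labeling)),
             function(v) is_valid_vector(labeling[v, ], instance$universe),
             logical(1)))
}

#' Parsimony score of a full labeling
#'
#' Sum over tree edges of the SCJ distance between the genomes at the two
#' ends; since the SCJ distance is a symmetric difference, the score
#' decomposes as a sum of per-adjacency Hamming costs over edges.
#'
#' @param instance An `scj_instance`.
#' @param labeling `n_vertex` x |A| 0-1 matrix (rows in vertex order).
#' @return Non-negative integer.
#' @export
tree_score <- function(instance, labeling) {
  e <- instance$tree$edges
  sum(abs(labeling[e[, 1L], , drop = FALSE] - labeling[e[, 2L], , drop = FALSE]))
}

# per-edge SCJ lengths of a labeling, named by edge
edge_lengths <- function(instance, labeling) {
  e <- instance$tree$edges
  d <- abs(labeling[e[, 1L], , drop = FALSE] - labeling[e[, 2L], , drop = FALSE])
  stats::setNames(as.integer(rowSums(d)), edge_names(instance$tree))
}
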