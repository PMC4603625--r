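#' @importFrom rlang abort warn
#' @importFrom tibble tibble as_tibble
NULL

# Extremities are strings "<block>h" / "<block>t"; adjacencies are canonical
# keys "<ext>|<ext>" with the two extremities in radix (C-locale) order, so
# equality and hashing are order-independent.

#' Construct an extremity label
#'
#' An extremity is one of the two ends of a synteny block: its head (`"h"`)
#' or its tail (`"t"`).
#'
#' @param block Character vector of block identifiers (arbitrary strings not
#'   containing `"|"`).
#' @param side `"h"` (head) or `"t"` (tail), recycled against `block`.
#' @return Character vector of extremity labels, e.g. `"5h"`.
#' @examples
#' extremity(c("1", "2"), c("h", "t"))
#' @export
extremity <- function(block, side) {
  if (!all(side %in% c("h", "t"))) {
    abort("`side` must be \"h\" or \"t\".")
  }
  if (any(grepl("|", block, fixed = TRUE))) {
    abort("block identifiers must not contain \"|\".")
  }
  paste0(block, side)
}

ext_block <- function(ext) substr(ext, 1L, nchar(ext) - 1L)
ext_side <- function(ext) substr(ext, nchar(ext), nchar(ext))

#' Construct adjacency keys from pairs of extremities
#'
#' An adjacency is an unordered pair of two distinct extremities that are
#' physically joined in a genome. The canonical key orders the two extremity
#' labels lexicographically (C locale), so `adjacency(a, b)` and
#' `adjacency(b, a)` are identical.
#'
#' @param ext1,ext2 Character vectors of extremity labels.
#' @return Character vector of canonical adjacency keys `"<ext>|<ext>"`.
#' @examples
#' adjacency("2t", "1h")  # "1h|2t"
#' @export
adjacency <- function(ext1, ext2) {
  if (length(ext1) != length(ext2)) {
    abort("`ext1` and `ext2` must have the same length.")
  }
  if (any(ext1 == ext2)) {
    abort("an adjacency joins two distinct extremities.")
  }
  vapply(
    seq_along(ext1),
    function(i) {
      p <- sort(c(ext1[i], ext2[i]), method = "radix")
      paste0(p[1L], "|", p[2L])
    },
    character(1)
  )
}

adj_ends <- function(adj) {
  if (length(adj) == 0L) {
    return(matrix(character(), nrow = 0L, ncol = 2L))
  }
  m <- matrix(unlist(strsplit(adj, "|", fixed = TRUE)), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("extremity1", "extremity2")
  m
}

#' Do two adjacencies conflict?
#'
#' Two distinct adjacencies conflict when they share an extremity; a set of
#' adjacencies represents a genome exactly when it is conflict-free.
#'
#' @param a,b Adjacency keys (see [adjacency()]).
#' @return Logical: `TRUE` iff `a != b` and they share at least one extremity.
#' @examples
#' adjacencies_conflict(adjacency("1h", "2t"), adjacency("1h", "2h"))  # TRUE
#' @export
adjacencies_conflict <- function(a, b) {
  if (a == b) {
    return(FALSE)
  }
  ea <- strsplit(a, "|", fixed = TRUE)[[1L]]
  eb <- strsplit(b, "|", fixed = TRUE)[[1L]]
  any(ea %in% eb)
}

#' Is a set of adjacencies conflict-free?
#'
#' @param adjs Character vector of adjacency keys.
#' @return Logical: `TRUE` iff no extremity occurs in more than one adjacency
#'   (duplicated keys count as reuse).
#' @export
is_conflict_free <- function(adjs) {
  if (anyDuplicated(adjs) > 0L) {
    return(FALSE)
  }
  !anyDuplicated(as.vector(adj_ends(adjs))) > 0L
}

#' Construct an SCJ genome
#'
#' A genome over a set of synteny blocks is a conflict-free set of
#' adjacencies; extremities not in any adjacency are telomeres and are kept
#' implicit.
#'
#' @param name Genome name.
#' @param blocks Character vector of block identifiers (the block universe;
#'   may include blocks with no adjacency).
#' @param adjacencies Character vector of adjacency keys over those blocks.
#' @return An object of class `scj_genome`: a list with elements `name`,
#'   `blocks` (sorted) and `adjacencies` (sorted canonical keys).
#' @examples
#' genome("G1", c("1", "2"), adjacency("1h", "2t"))
#' @export
genome <- function(name, blocks, adjacencies = character()) {
  blocks <- sort(unique(as.character(blocks)), method = "radix")
  adjacencies <- sort(unique(as.character(adjacencies)), method = "radix")
  ends <- as.vector(adj_ends(adjacencies))
  if (anyDuplicated(ends) > 0L) {
    dup <- ends[duplicated(ends)][1L]
    abort(sprintf("adjacency set is not conflict-free: extremity %s is reused.", dup))
  }
  bad <- setdiff(ext_block(ends), blocks)
  if (length(bad) > 0L) {
    abort(sprintf("adjacency references unknown block(s): %s.", paste(bad, collapse = ", ")))
  }
  structure(
    list(name = as.character(name), blocks = blocks, adjacencies = adjacencies),
    class = "scj_genome"
  )
}

#' @export
print.scj_genome <- function(x, ...) {
  cat(sprintf(
    "<scj_genome> %s: %d blocks, %d adjacencies\n",
    x$name, length(x$blocks), length(x$adjacencies)
  ))
  if (length(x$adjacencies) > 0L) {
    cat(" ", paste(x$adjacencies, collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
as_tibble.scj_genome <- function(x, ...) {
  ends <- adj_ends(x$adjacencies)
  tibble(
    genome = rep(x$name, nrow(ends)),
    extremity1 = ends[, 1L],
    extremity2 = ends[, 2L]
  )
}

#' SCJ distance between two genomes
#'
#' The Single Cut or Join distance is the size of the symmetric difference of
#' the two adjacency sets: every adjacency private to one genome costs exactly
#' one cut or one join.
#'
#' @param g1,g2 `scj_genome` objects over the same block set.
#' @return Non-negative integer distance.
#' @examples
#' g1 <- genome("a", 1:2, adjacency("1h", "2t"))
#' g2 <- genome("b", 1:2, adjacency("1h", "2h"))
#' scj_distance(g1, g2)  # 2
#' @export
scj_distance <- function(g1, g2) {
  stopifnot(inherits(g1, "scj_genome"), inherits(g2, "scj_genome"))
  if (!identical(g1$blocks, g2$blocks)) {
    abort("genomes are over different block sets.")
  }
  length(setdiff(g1$adjacencies, g2$adjacencies)) +
    length(setdiff(g2$adjacencies, g1$adjacencies))
}

#' Build an adjacency universe
#'
#' The universe indexes the distinct adjacencies observed across a collection
#' of genomes (the search space of the sampler); order is first-seen over the
#' genomes in the order given, so runs are reproducible for identical input.
#'
#' @param genomes List of `scj_genome` objects.
#' @return An `scj_universe`: list with `keys` (character vector of adjacency
#'   keys in first-seen order), `ends` (|A| x 2 matrix of extremities) and
#'   `conflicts` (list mapping each coordinate to the coordinates it
#'   conflicts with).
#' @export
adjacency_universe <- function(genomes) {
  keys <- unique(unlist(lapply(genomes, function(g) g$adjacencies), use.names = FALSE))
  if (is.null(keys)) keys <- character()
  new_universe(keys)
}

new_universe <- function(keys) {
  ends <- adj_ends(keys)
  n <- length(keys)
  conflicts <- vector("list", n)
  if (n > 0L) {
    for (i in seq_len(n)) {
      hit <- which(ends[, 1L] %in% ends[i, ] | ends[, 2L] %in% ends[i, ])
      conflicts[[i]] <- setdiff(hit, i)
    }
  }
  structure(list(keys = keys, ends = ends, conflicts = conflicts),
            class = "scj_universe")
}

#' @export
print.scj_universe <- function(x, ...) {
  cat(sprintf("<scj_universe> %d adjacencies\n", length(x$keys)))
  invisible(x)
}

#' Encode a genome as a 0-1 vector over a universe
#'
#' Coordinate i is 1 iff the universe's i-th adjacency is present in the
#' genome. A 0-1 vector is valid when no two set coordinates index
#' conflicting adjacencies; every valid vector represents a genome.
#'
#' @param g An `scj_genome`.
#' @param universe An `scj_universe` containing all of `g`'s adjacencies.
#' @return Integer 0/1 vector of length `length(universe$keys)`.
#' @export
encode_genome <- function(g, universe) {
  stopifnot(inherits(g, "scj_genome"), inherits(universe, "scj_universe"))
  missing <- setdiff(g$adjacencies, universe$keys)
  if (length(missing) > 0L) {
    abort(sprintf("adjacency not in universe: %s.", paste(missing, collapse = ", ")))
  }
  as.integer(universe$keys %in% g$adjacencies)
}

#' @rdname encode_genome
#' @param bits Integer 0/1 vector over `universe`.
#' @param blocks Block set for the decoded genome.
#' @param name Name for the decoded genome.
#' @export
decode_genome <- function(bits, universe, blocks, name = "decoded") {
  stopifnot(length(bits) == length(universe$keys))
  genome(name, blocks, universe$keys[bits != 0L])
}

#' Is a 0-1 vector valid over a universe?
#'
#' @inheritParams decode_genome
#' @return `TRUE` iff no two set coordinates conflict.
#' @export
is_valid_vector <- function(bits, universe) {
  on <- which(bits != 0L)
  for (i in on) {
    if (any(bits[universe$conflicts[[i]]] != 0L)) {
      return(FALSE)
    }
  }
  TRUE
}
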