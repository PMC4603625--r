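# Conversions between the adjacency-set representation and signed
# chromosome lists (GRIMM-style). A block +b presents its tail on the left
# and its head on the right; -b the reverse. An adjacency joins the right
# extremity of each element to the left extremity of its successor; a
# circular chromosome also joins last-right to first-left. Linear chromosome
# ends are telomeres and produce no adjacency.

parse_signed <- function(tok) {
  sign <- ifelse(startsWith(tok, "-"), "-", "+")
  block <- sub("^[+-]", "", tok)
  if (any(block == "")) {
    abort("empty block token in chromosome.")
  }
  list(sign = sign, block = block)
}

# left/right exposed extremities of a signed block
signed_ends <- function(tok) {
  p <- parse_signed(tok)
  left <- extremity(p$block, ifelse(p$sign == "+", "t", "h"))
  right <- extremity(p$block, ifelse(p$sign == "+", "h", "t"))
  list(left = left, right = right, block = p$block)
}

#' Build a genome from signed chromosome lists
#'
#' @param name Genome name.
#' @param chromosomes List of chromosomes; each chromosome is a list with
#'   `blocks`, a character vector of signed block tokens (`"+5"`, `"-x"`;
#'   a bare token means `+`), and `circular`, a logical flag.
#' @param blocks Optional full block universe; defaults to the blocks seen in
#'   `chromosomes`. Extra blocks become singleton linear chromosomes
#'   (telomeres only).
#' @return An [genome()] object.
#' @examples
#' genome_from_chromosomes("g", list(list(blocks = c("+1", "-2"), circular = FALSE)))
#' @export
genome_from_chromosomes <- function(name, chromosomes, blocks = NULL) {
  all_blocks <- character()
  adjs <- character()
  for (chr in chromosomes) {
    toks <- chr$blocks
    circular <- isTRUE(chr$circular)
    se <- signed_ends(toks)
    if (any(se$block %in% all_blocks) || anyDuplicated(se$block) > 0L) {
      abort("a block appears more than once across chromosomes.")
    }
    all_blocks <- c(all_blocks, se$block)
    n <- length(toks)
    if (n > 1L) {
      adjs <- c(adjs, adjacency(se$right[-n], se$left[-1L]))
    }
    if (circular) {
      adjs <- c(adjs, adjacency(se$right[n], se$left[1L]))
    }
  }
  if (!is.null(blocks)) {
    if (!all(all_blocks %in% as.character(blocks))) {
      abort("chromosomes use blocks outside the supplied block universe.")
    }
    all_blocks <- as.character(blocks)
  }
  genome(name, all_blocks, adjs)
}

#' Decompose a genome into chromosomes
#'
#' Inverse of [genome_from_chromosomes()] up to chromosome order, orientation
#' flip of linear chromosomes, and rotation/flip of circular ones. Telomeric
#' blocks come out as singleton linear chromosomes.
#'
#' @param g An `scj_genome`.
#' @return List of chromosomes in the [genome_from_chromosomes()] format,
#'   deterministically ordered.
#' @export
as_chromosomes <- function(g) {
  stopifnot(inherits(g, "scj_genome"))
  ends <- adj_ends(g$adjacencies)
  partner <- c(
    stats::setNames(ends[, 2L], ends[, 1L]),
    stats::setNames(ends[, 1L], ends[, 2L])
  )
  visited <- stats::setNames(rep(FALSE, length(g$blocks)), g$blocks)
  chroms <- list()

  walk <- function(start_ext) {
    # start_ext is the left extremity of the first block; returns signed walk
    toks <- character()
    ext <- start_ext
    repeat {
      b <- ext_block(ext)
      visited[b] <<- TRUE
      toks <- c(toks, paste0(ifelse(ext_side(ext) == "t", "+", "-"), b))
      right <- extremity(b, ifelse(ext_side(ext) == "t", "h", "t"))
      nxt <- partner[right]
      if (is.na(nxt)) {
        return(list(toks = toks, closed = FALSE))
      }
      if (ext_block(nxt) == ext_block(start_ext) && nxt == start_ext) {
        return(list(toks = toks, closed = TRUE))
      }
      ext <- nxt
    }
  }

  # linear chromosomes: start from telomeric extremities, sorted
  all_ext <- c(extremity(g$blocks, "t"), extremity(g$blocks, "h"))
  telomeric <- sort(setdiff(all_ext, names(partner)), method = "radix")
  # prefer starting at a tail so unrearranged blocks come out forward
  telomeric <- telomeric[order(ext_side(telomeric) != "t", telomeric)]
  for (te in telomeric) {
    if (visited[ext_block(te)]) next
    w <- walk(te)
    chroms[[length(chroms) + 1L]] <- list(blocks = w$toks, circular = FALSE)
  }
  # remaining blocks lie on circular chromosomes
  for (b in g$blocks) {
    if (visited[b]) next
    w <- walk(extremity(b, "t"))
    stopifnot(w$closed)
    chroms[[length(chroms) + 1L]] <- list(blocks = w$toks, circular = TRUE)
  }
  chroms
}

#' Read and write GRIMM-style genome files
#'
#' The GRIMM format holds one or more genomes: a `>name` line starts a
#' genome, then whitespace-separated signed blocks form chromosomes, each
#' terminated by `$` (linear) or `@` (circular). All genomes in one file
#' share a block universe (the union of blocks seen; blocks missing from a
#' genome are telomeric singletons there).
#'
#' @param path File path.
#' @return `read_grimm()`: named list of `scj_genome` objects over the common
#'   block set.
#' @export
read_grimm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  toks <- unlist(strsplit(trimws(lines), "\\s+"))
  toks <- toks[toks != ""]
  if (length(toks) == 0L || !startsWith(toks[1L], ">")) {
    abort("GRIMM file must start with a '>name' line.")
  }
  raw <- list()
  name <- NULL
  chrom <- character()
  chroms <- list()
  flush_genome <- function() {
    if (length(chrom) > 0L) {
      abort(sprintf("genome %s: unterminated chromosome (missing $ or @).", name))
    }
    raw[[name]] <<- chroms
    chroms <<- list()
  }
  for (tk in toks) {
    if (startsWith(tk, ">")) {
      if (!is.null(name)) flush_genome()
      name <- substring(tk, 2L)
      if (name == "") abort("empty genome name after '>'.")
      if (name %in% names(raw)) abort(sprintf("duplicate genome name %s.", name))
    } else if (tk %in% c("$", "@")) {
      if (length(chrom) == 0L) abort(sprintf("genome %s: empty chromosome.", name))
      chroms[[length(chroms) + 1L]] <- list(blocks = chrom, circular = tk == "@")
      chrom <- character()
    } else {
      if (is.null(name)) abort("block token before any '>name' line.")
      chrom <- c(chrom, tk)
    }
  }
  flush_genome()
  blocks <- sort(unique(unlist(lapply(raw, function(ch) {
    unlist(lapply(ch, function(c1) parse_signed(c1$blocks)$block))
  }))), method = "radix")
  out <- lapply(names(raw), function(nm) {
    genome_from_chromosomes(nm, raw[[nm]], blocks = blocks)
  })
  stats::setNames(out, names(raw))
}

#' @rdname read_grimm
#' @param genomes Named list of `scj_genome` objects.
#' @export
write_grimm <- function(genomes, path) {
  lines <- character()
  for (g in genomes) {
    lines <- c(lines, paste0(">", g$name))
    for (chr in as_chromosomes(g)) {
      lines <- c(lines, paste(
        paste(chr$blocks, collapse = " "),
        if (chr$circular) "@" else "$"
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write adjacency tables
#'
#' A TSV with columns `genome`, `extremity1`, `extremity2`, one adjacency per
#' row. A row with both extremities equal to `"-"` declares a genome with no
#' adjacencies (so empty genomes survive the round trip). The block set is
#' the union of blocks referenced by the extremities unless `blocks` is
#' given.
#'
#' @param path File path.
#' @param blocks Optional block universe.
#' @return `read_adjacency_table()`: named list of `scj_genome`s.
#' @export
read_adjacency_table <- function(path, blocks = NULL) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("genome", "extremity1", "extremity2")
  if (!all(need %in% names(df))) {
    abort("adjacency table needs columns genome, extremity1, extremity2.")
  }
  genomes_from_table(df, blocks = blocks)
}

#' @rdname read_adjacency_table
#' @param df Data frame with columns `genome`, `extremity1`, `extremity2`.
#' @export
genomes_from_table <- function(df, blocks = NULL) {
  placeholder <- df$extremity1 == "-" & df$extremity2 == "-"
  keys <- character(nrow(df))
  keys[!placeholder] <- adjacency(df$extremity1[!placeholder], df$extremity2[!placeholder])
  if (is.null(blocks)) {
    blocks <- sort(unique(ext_block(as.vector(adj_ends(keys[!placeholder])))),
                   method = "radix")
  }
  names <- unique(df$genome)
  out <- lapply(names, function(nm) {
    genome(nm, blocks, keys[df$genome == nm & !placeholder])
  })
  stats::setNames(out, names)
}

#' @rdname read_adjacency_table
#' @param genomes Named list of `scj_genome`s (or a single one).
#' @export
write_adjacency_table <- function(genomes, path) {
  if (inherits(genomes, "scj_genome")) genomes <- list(genomes)
  df <- do.call(rbind, lapply(genomes, function(g) {
    tb <- as_tibble(g)
    if (nrow(tb) == 0L) {
      tb <- tibble(genome = g$name, extremity1 = "-", extremity2 = "-")
    }
    tb
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
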