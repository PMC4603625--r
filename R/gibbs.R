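# Gibbs sampling over the most parsimonious valid labelings.
#
# One step: pick an adjacency coordinate i uniformly; run the
# Sankoff-Rousseau dynamic program on the leaves' 0/1 states for that
# coordinate; build the metagraph of (vertex, character) states, keeping a
# "present" state at an internal vertex only when writing it into the
# current labeling keeps the vertex's genome conflict-free; weight each
# state by the number of valid optimal sub-assignments below it; and draw a
# new assignment of coordinate i top-down proportionally to those weights.
# The draw is exactly uniform over all most parsimonious valid labelings
# that agree with the current one off coordinate i.
#
# Weights are doubles holding exact integers; per-coordinate solution
# counts are at most 2^(number of internal nodes), and a guard aborts if a
# weight nears 2^52.

WEIGHT_CAP <- 2^52

# metagraph + weights for coordinate i under the current labeling.
# Returns per-vertex presence and weights; leaves carry only their observed
# state with weight 1.
build_metagraph <- function(instance, labeling, i) {
  tree <- instance$tree
  nt <- tree$n_tip
  chars <- labeling[, i]
  s <- sankoff(tree, chars[seq_len(nt)])
  conf <- instance$universe$conflicts[[i]]

  present0 <- logical(tree$n_vertex)
  present1 <- logical(tree$n_vertex)
  lt <- seq_len(nt)
  present0[lt] <- chars[lt] == 0L
  present1[lt] <- chars[lt] == 1L
  internal <- setdiff(seq_len(tree$n_vertex), lt)
  present0[internal] <- TRUE
  for (v in internal) {
    present1[v] <- length(conf) == 0L || all(labeling[v, conf] == 0L)
  }

  m0 <- numeric(tree$n_vertex)
  m1 <- numeric(tree$n_vertex)
  m0[lt][present0[lt]] <- 1
  m1[lt][present1[lt]] <- 1

  side_weight <- function(u, kp) {
    # total weight of u-side in-neighbors of node (v, kp)
    c0 <- s[u, 1L] + (kp != 0L)
    c1 <- s[u, 2L] + (kp != 1L)
    cmin <- min(c0, c1)
    w <- 0
    if (present0[u] && c0 == cmin) w <- w + m0[u]
    if (present1[u] && c1 == cmin) w <- w + m1[u]
    w
  }

  for (v in tree$postorder) {
    if (v <= nt) next
    u1 <- tree$children[v, 1L]
    u2 <- tree$children[v, 2L]
    if (present0[v]) m0[v] <- side_weight(u1, 0L) * side_weight(u2, 0L)
    if (present1[v]) m1[v] <- side_weight(u1, 1L) * side_weight(u2, 1L)
  }
  if (max(m0, m1) >= WEIGHT_CAP) {
    abort("metagraph weight exceeds the exactly representable range.")
  }
  list(s = s, present0 = present0, present1 = present1,
       m0 = m0, m1 = m1, side_weight = side_weight)
}

draw_weighted <- function(values, weights) {
  if (length(values) == 1L) {
    return(values)
  }
  values[sample.int(length(values), 1L, prob = weights)]
}

#' Resample one adjacency coordinate of a most parsimonious labeling
#'
#' The Gibbs conditional: draws uniformly from all most parsimonious valid
#' labelings that agree with `labeling` in every coordinate except `i`.
#' The root state is drawn among the valid states attaining the
#' per-coordinate Sankoff minimum, proportionally to the number of valid
#' optimal sub-assignments; the choice is then propagated down the tree by
#' weighted draws among each child's optimal states.
#'
#' @param instance An `scj_instance`.
#' @param labeling Current most parsimonious valid labeling (0-1 matrix).
#' @param i Coordinate (adjacency index in the universe).
#' @return A labeling matrix differing from the input only in coordinate `i`
#'   of internal vertices; same parsimony score, still valid.
#' @export
resample_coordinate <- function(instance, labeling, i) {
  tree <- instance$tree
  nt <- tree$n_tip
  nv <- tree$n_vertex
  root <- tree$root
  chars <- labeling[, i]
  conf <- instance$universe$conflicts[[i]]
  nconf <- length(conf)

  # Sankoff costs, state presence and enumeration weights, bottom-up.
  # INF is a plain large double here; costs are bounded by the edge count.
  s0 <- numeric(nv); s1 <- numeric(nv)
  p0 <- logical(nv); p1 <- logical(nv)
  m0 <- numeric(nv); m1 <- numeric(nv)
  lt <- seq_len(nt)
  leaf1 <- chars[lt] == 1L
  s0[lt] <- ifelse(leaf1, INF, 0)
  s1[lt] <- ifelse(leaf1, 0, INF)
  p0[lt] <- !leaf1; p1[lt] <- leaf1
  m0[lt][!leaf1] <- 1; m1[lt][leaf1] <- 1
  ch <- tree$children
  for (v in tree$postorder) {
    if (v <= nt) next
    u1 <- ch[v, 1L]; u2 <- ch[v, 2L]
    a0 <- min(s0[u1], s1[u1] + 1); b0 <- min(s0[u2], s1[u2] + 1)
    a1 <- min(s0[u1] + 1, s1[u1]); b1 <- min(s0[u2] + 1, s1[u2])
    s0[v] <- a0 + b0
    s1[v] <- a1 + b1
    p0[v] <- TRUE
    p1[v] <- nconf == 0L || !any(labeling[v, conf] == 1L)
    w1 <- 0
    if (p0[u1] && s0[u1] == a0) w1 <- w1 + m0[u1]
    if (p1[u1] && s1[u1] + 1 == a0) w1 <- w1 + m1[u1]
    w2 <- 0
    if (p0[u2] && s0[u2] == b0) w2 <- w2 + m0[u2]
    if (p1[u2] && s1[u2] + 1 == b0) w2 <- w2 + m1[u2]
    m0[v] <- w1 * w2
    if (p1[v]) {
      w1 <- 0
      if (p0[u1] && s0[u1] + 1 == a1) w1 <- w1 + m0[u1]
      if (p1[u1] && s1[u1] == a1) w1 <- w1 + m1[u1]
      w2 <- 0
      if (p0[u2] && s0[u2] + 1 == b1) w2 <- w2 + m0[u2]
      if (p1[u2] && s1[u2] == b1) w2 <- w2 + m1[u2]
      m1[v] <- w1 * w2
    }
  }
  if (m0[root] >= WEIGHT_CAP || m1[root] >= WEIGHT_CAP) {
    abort("metagraph weight exceeds the exactly representable range.")
  }

  smin <- min(s0[root], s1[root])
  ks <- integer(0)
  ws <- numeric(0)
  if (p0[root] && m0[root] > 0 && s0[root] == smin) {
    ks <- c(ks, 0L); ws <- c(ws, m0[root])
  }
  if (p1[root] && m1[root] > 0 && s1[root] == smin) {
    ks <- c(ks, 1L); ws <- c(ws, m1[root])
  }
  if (length(ks) == 0L) {
    abort("internal inconsistency: current labeling unreachable in its own metagraph.")
  }

  chosen <- integer(nv)
  chosen[lt] <- chars[lt]
  chosen[root] <- draw_weighted(ks, ws)
  for (v in tree$preorder) {
    if (v <= nt) next
    kp <- chosen[v]
    for (u in ch[v, ]) {
      c0 <- s0[u] + (kp != 0L)
      c1 <- s1[u] + (kp != 1L)
      cmin <- min(c0, c1)
      ku <- integer(0)
      wu <- numeric(0)
      if (p0[u] && c0 == cmin && m0[u] > 0) {
        ku <- c(ku, 0L); wu <- c(wu, m0[u])
      }
      if (p1[u] && c1 == cmin && m1[u] > 0) {
        ku <- c(ku, 1L); wu <- c(wu, m1[u])
      }
      if (length(ku) == 0L) {
        abort("internal inconsistency: dead end in metagraph backtrace.")
      }
      chosen[u] <- draw_weighted(ku, wu)
    }
  }
  internal <- (nt + 1L):nv
  labeling[internal, i] <- chosen[internal]
  labeling
}

#' One Gibbs sweep step
#'
#' Draws a coordinate uniformly from the adjacency universe and resamples it
#' with [resample_coordinate()].
#'
#' @inheritParams resample_coordinate
#' @return Updated labeling matrix.
#' @export
gibbs_step <- function(instance, labeling) {
  nA <- length(instance$universe$keys)
  if (nA == 0L) {
    return(labeling)
  }
  resample_coordinate(instance, labeling, sample.int(nA, 1L))
}

#' Run the Gibbs sampler over most parsimonious labelings
#'
#' Starts from the canonical Fitch labeling, performs `steps` Gibbs steps,
#' and records the state after every `thin`-th step once `burn_in` steps
#' have passed. Every recorded state is checked to be valid and to have the
#' same parsimony score as the start (the chain moves only between most
#' parsimonious labelings). With `steps = 0` the single record is the
#' canonical labeling itself.
#'
#' @param instance An `scj_instance` from [bind_genomes()].
#' @param steps Number of Gibbs steps.
#' @param thin Record every `thin`-th step (default 1).
#' @param burn_in Steps to discard before recording (default 0; investigation
#'   of mixing needs the whole trajectory).
#' @param seed Integer seed driving coordinate choice and all backtrace
#'   draws; recorded in the result.
#' @return An `scj_gibbs` object: list with `instance`, `score`, `samples`
#'   (list of internal-vertex 0-1 matrices), `sample_steps`, `edge_lengths`
#'   (samples x edges integer matrix, columns named `parent->child`),
#'   `initial` (the canonical labeling) and `config`.
#' @export
run_gibbs <- function(instance, steps, thin = 1L, burn_in = 0L, seed = 1L) {
  stopifnot(inherits(instance, "scj_instance"), steps >= 0L, thin >= 1L, burn_in >= 0L)
  set.seed(seed)
  tree <- instance$tree
  internal <- (tree$n_tip + 1L):tree$n_vertex
  lab <- canonical_labeling(instance)
  score <- tree_score(instance, lab)
  if (!labeling_is_valid(instance, lab)) {
    abort("canonical labeling is not valid; this is a bug.")
  }

  record_steps <- if (steps >= burn_in + thin) {
    seq.int(burn_in + thin, steps, by = thin)
  } else {
    steps
  }
  samples <- vector("list", length(record_steps))
  elen <- matrix(0L, nrow = length(record_steps), ncol = nrow(tree$edges),
                 dimnames = list(NULL, edge_names(tree)))
  ri <- 1L
  record <- function(step) {
    el <- edge_lengths(instance, lab)
    if (sum(el) != score) {
      abort("score drifted during sampling; this is a bug.")
    }
    samples[[ri]] <<- lab[internal, , drop = FALSE]
    elen[ri, ] <<- el
    ri <<- ri + 1L
  }
  if (steps == 0L || length(record_steps) == 0L) {
    record(0L)
  } else {
    next_rec <- 1L
    for (step in seq_len(steps)) {
      lab <- gibbs_step(instance, lab)
      if (next_rec <= length(record_steps) && step == record_steps[next_rec]) {
        record(step)
        next_rec <- next_rec + 1L
      }
    }
    if (ri <= length(record_steps)) {
      record(steps)  # steps < burn_in + thin: keep the final state
    }
  }

  structure(
    list(
      instance = instance, score = score, samples = samples,
      sample_steps = record_steps, edge_lengths = elen,
      initial = lab_initial(instance),
      config = list(steps = steps, thin = thin, burn_in = burn_in, seed = seed)
    ),
    class = "scj_gibbs"
  )
}

lab_initial <- function(instance) canonical_labeling(instance)

#' @export
print.scj_gibbs <- function(x, ...) {
  cat(sprintf(
    "<scj_gibbs> %d samples from a %d-step chain (thin %d, burn-in %d, seed %d)\n",
    length(x$samples), x$config$steps, x$config$thin, x$config$burn_in, x$config$seed
  ))
  cat(sprintf("  parsimony score %d over %d edges, %d adjacencies\n",
              x$score, nrow(x$instance$tree$edges), length(x$instance$universe$keys)))
  invisible(x)
}

# full labeling matrix of sample j
sample_labeling <- function(chain, j) {
  new_labeling(chain$instance, chain$samples[[j]])
}

# compact key identifying a sample's internal assignment
labeling_key <- function(internal_bits) {
  paste(internal_bits, collapse = "")
}
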