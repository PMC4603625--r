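# Convergence diagnostics for the Gibbs chain: per-edge SCJ-length traces,
# their autocorrelation, and goodness-of-fit of the sampled labelings
# against an enumerated solution set.

#' Per-edge SCJ-length traces of a chain
#'
#' One series per tree edge, giving the number of SCJ operations on that
#' edge in each recorded sample. Per sample the lengths sum to the chain's
#' constant parsimony score — only the split of the score across edges
#' moves.
#'
#' @param chain An `scj_gibbs` object.
#' @return Tibble with columns `sample` (index), `step` (Gibbs step at which
#'   the sample was recorded), `edge` and `length`.
#' @export
edge_traces <- function(chain) {
  stopifnot(inherits(chain, "scj_gibbs"))
  el <- chain$edge_lengths
  sums <- rowSums(el)
  if (any(sums != chain$score)) {
    abort("per-sample edge lengths do not sum to the chain score; this is a bug.")
  }
  tibble(
    sample = rep(seq_len(nrow(el)), times = ncol(el)),
    step = rep(chain$sample_steps, times = ncol(el)),
    edge = rep(colnames(el), each = nrow(el)),
    length = as.integer(el)
  )
}

#' Sample autocorrelation of a trace
#'
#' Standard biased (divide-by-n) lag-k sample autocorrelation, the usual
#' MCMC convention. A zero-variance series returns 0 at all positive lags —
#' a constant trace is reported as instantly mixed rather than undefined.
#'
#' @param series Numeric vector.
#' @param max_lag Largest lag (must be smaller than the series length).
#' @return Numeric vector of length `max_lag + 1` (lags `0..max_lag`);
#'   lag 0 is 1 for any non-constant series.
#' @export
trace_autocorrelation <- function(series, max_lag) {
  n <- length(series)
  if (max_lag >= n) {
    abort("`max_lag` must be smaller than the series length.")
  }
  if (stats::var(series) == 0) {
    return(c(1, rep(0, max_lag)))
  }
  as.vector(stats::acf(series, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
}

#' Autocorrelation table for all edge traces
#'
#' @param chain An `scj_gibbs` object.
#' @param max_lag Largest lag.
#' @return Tibble with columns `edge`, `lag`, `autocorrelation`.
#' @export
chain_autocorrelation <- function(chain, max_lag) {
  el <- chain$edge_lengths
  out <- lapply(colnames(el), function(e) {
    tibble(
      edge = e,
      lag = 0:max_lag,
      autocorrelation = trace_autocorrelation(el[, e], max_lag)
    )
  })
  do.call(rbind, out)
}

#' Test sampled labelings against a uniform target
#'
#' Matches every recorded sample to a member of the enumerated solution set
#' (erroring if any sample falls outside it — that would be a sampler bug,
#' not bad mixing) and compares the empirical counts with the uniform
#' distribution via a chi-square goodness-of-fit test and the total
#' variation distance (half the L1 distance between the empirical and
#' uniform laws).
#'
#' @param chain An `scj_gibbs` object.
#' @param solution_set Labelings from [enumerate_optimal_labelings()] (its
#'   `labelings` element), or any list of full labeling matrices.
#' @return One-row tibble: `n_samples`, `n_solutions`, `statistic`,
#'   `p_value`, `tv_distance`.
#' @export
uniformity_test <- function(chain, solution_set) {
  stopifnot(inherits(chain, "scj_gibbs"), length(solution_set) >= 1L)
  internal <- (chain$instance$tree$n_tip + 1L):chain$instance$tree$n_vertex
  sol_keys <- vapply(solution_set, function(lab) {
    labeling_key(lab[internal, , drop = FALSE])
  }, character(1))
  stopifnot(anyDuplicated(sol_keys) == 0L)
  samp_keys <- vapply(chain$samples, labeling_key, character(1))
  outside <- setdiff(samp_keys, sol_keys)
  if (length(outside) > 0L) {
    abort("a sampled labeling is outside the solution set; the sampler is broken.")
  }
  counts <- table(factor(samp_keys, levels = sol_keys))
  k <- length(sol_keys)
  n <- length(samp_keys)
  chisq <- sum((as.numeric(counts) - n / k)^2 / (n / k))
  p <- stats::pchisq(chisq, df = k - 1L, lower.tail = FALSE)
  tv <- sum(abs(as.numeric(counts) / n - 1 / k)) / 2
  tibble(
    n_samples = n, n_solutions = k,
    statistic = chisq, p_value = p, tv_distance = tv
  )
}
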