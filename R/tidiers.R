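#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a Gibbs chain into its edge-length traces
#'
#' @param x An `scj_gibbs` object.
#' @param ... Unused.
#' @return Long tibble, one row per (sample, edge): columns `sample`,
#'   `step`, `edge`, `length`. See [edge_traces()].
#' @exportS3Method generics::tidy
tidy.scj_gibbs <- function(x, ...) {
  edge_traces(x)
}

#' One-row summary of a Gibbs chain
#'
#' @param x An `scj_gibbs` object.
#' @param ... Unused.
#' @return Tibble with `score` (the constant parsimony score), `n_samples`,
#'   `n_distinct_labelings` observed, `steps`, `thin`, `burn_in`, `seed`,
#'   `n_adjacencies` and `n_edges`.
#' @exportS3Method generics::glance
glance.scj_gibbs <- function(x, ...) {
  keys <- vapply(x$samples, labeling_key, character(1))
  tibble(
    score = x$score,
    n_samples = length(x$samples),
    n_distinct_labelings = length(unique(keys)),
    steps = x$config$steps,
    thin = x$config$thin,
    burn_in = x$config$burn_in,
    seed = x$config$seed,
    n_adjacencies = length(x$instance$universe$keys),
    n_edges = nrow(x$instance$tree$edges)
  )
}

#' Plot chain diagnostics
#'
#' `type = "trace"` draws the per-edge SCJ-length traces against the Gibbs
#' step; `type = "autocorrelation"` the per-edge lag autocorrelations.
#'
#' @param object An `scj_gibbs` object.
#' @param type `"trace"` or `"autocorrelation"`.
#' @param max_lag Largest lag for the autocorrelation panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scj_gibbs <- function(object, type = c("trace", "autocorrelation"),
                               max_lag = NULL, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    df <- edge_traces(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$length,
                                     colour = .data$edge)) +
      ggplot2::geom_line(alpha = 0.8) +
      ggplot2::labs(x = "Gibbs step", y = "SCJ operations on edge",
                    colour = "edge") +
      ggplot2::theme_minimal()
  } else {
    if (is.null(max_lag)) {
      max_lag <- min(40L, length(object$samples) - 1L)
    }
    df <- chain_autocorrelation(object, max_lag)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$autocorrelation)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~edge) +
      ggplot2::labs(x = "lag (in recorded samples)", y = "autocorrelation") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom rlang .data
NULL
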