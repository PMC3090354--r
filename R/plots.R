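# ggplot2 views of the result objects.

#' Plot a signal/noise benchmark curve
#'
#' Domains per protein ("signal") against the noise axis — estimated FDR for
#' the shuffling benchmark, mean ortholog coherence for the coherence
#' benchmark — one curve per method. Better methods sit higher.
#'
#' @param results Tibble with columns `method`, `signal` and either `fdr` or
#'   `coherence` (e.g. stacked [glance()] rows).
#' @param noise Name of the noise column (default auto-detected).
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results, noise = NULL) {
  results <- tibble::as_tibble(results)
  if (is.null(noise)) {
    noise <- intersect(c("fdr", "mean_coherence", "coherence"), names(results))[1]
    if (is.na(noise)) abort("no fdr/coherence column found", class = "dpucr_usage")
  }
  if (!"method" %in% names(results)) results$method <- "method"
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data[[noise]], y = .data$signal,
                               colour = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (noise == "fdr") "estimated FDR" else "ortholog coherence",
                  y = "domains per protein", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_benchmark autoplot method for one FDR experiment:
#'   per-protein shuffled vs real prediction counts.
#' @param object An `fdr_experiment`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.fdr_experiment <- function(object, ...) {
  ggplot2::ggplot(object$records, ggplot2::aes(x = .data$R, y = .data$A)) +
    ggplot2::geom_abline(slope = object$fdr, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "predictions on real protein (R)",
                  y = "mean predictions on shuffled portion (A)",
                  title = sprintf("estimated FDR = %.3g", object$fdr)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_benchmark autoplot method for a coherence experiment:
#'   distribution of per-domain coherence scores.
#' @exportS3Method ggplot2::autoplot
autoplot.coherence_experiment <- function(object, ...) {
  ggplot2::ggplot(object$per_domain, ggplot2::aes(x = .data$coherence)) +
    ggplot2::geom_histogram(binwidth = 0.1, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "per-domain ortholog coherence", y = "domains",
                  title = sprintf("mean coherence = %.3g, %.3g domains/protein",
                                  object$mean_coherence,
                                  object$domains_per_protein)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_benchmark autoplot method for a context network: the
#'   distribution of observed-pair scores and the unobserved penalty.
#' @exportS3Method ggplot2::autoplot
autoplot.context_network <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "darkorange", colour = "white") +
    ggplot2::geom_vline(xintercept = object$unobserved_penalty, linetype = 2) +
    ggplot2::labs(x = "context score (bits)", y = "observed pairs",
                  title = sprintf("unobserved-pair penalty = %.3g bits",
                                  object$unobserved_penalty)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
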