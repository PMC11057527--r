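#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the cost distributions of a study
#'
#' Histograms of the observed-max-normalized one-sided RF, CA and CS costs
#' across the sampled tree pairs.  RF piles up at its maximum while CA and CS
#' spread over a visibly broader range.
#'
#' @param object An `aff_study`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aff_study <- function(object, bins = 40, ...) {
  p <- object$pairs
  long <- dplyr::bind_rows(
    tibble::tibble(cost = "RF", value = p$rf_norm),
    tibble::tibble(cost = "CA", value = p$ca_norm),
    tibble::tibble(cost = "CS", value = p$cs_norm))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$cost)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::facet_wrap(~cost, scales = "free_y") +
    ggplot2::labs(x = "cost / observed maximum", y = "tree pairs",
                  title = sprintf("Cost distributions over %d pairs, n = %d",
                                  object$params$reps, object$params$n)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a robustness curve
#'
#' Mean normalized cost from the start tree as a function of the number of
#' accumulated edit operations, one line per cost.
#'
#' @param object An `aff_robustness`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aff_robustness <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$step, y = .data$mean,
                               colour = toupper(.data$cost))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("%s operations applied", toupper(object$params$op)),
                  y = sprintf("mean cost (%s-normalized)", object$params$normalize),
                  colour = "cost",
                  title = sprintf("Robustness to %s edits, n = %d, %d start trees",
                                  toupper(object$params$op), object$params$n,
                                  object$params$num_trees)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
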