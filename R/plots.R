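# ggplot2 displays for the result objects.

#' Plot per-site evidence for an HLA LOH call
#'
#' Shows the b-allele frequency of every discriminating site along the
#' allele-1 coordinate, one panel per gene, with the balanced expectation
#' (BAF 0.5) as a dashed line. Deviation of a gene's site cloud from 0.5
#' is the visual signature of allelic imbalance.
#'
#' @param object An `hla_loh_call`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hla_loh_call
#' @export
autoplot.hla_loh_call <- function(object, ...) {
  if (nrow(object$sites) == 0) {
    abort("no per-site evidence to plot (all genes flagged?)")
  }
  ggplot2::ggplot(object$sites,
                  ggplot2::aes(x = .data$pos1, y = .data$baf)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~gene, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position on allele 1 (bp)",
                  y = "B-allele frequency (allele 1)",
                  title = "Discriminating-site BAF by gene") +
    ggplot2::theme_minimal()
}

#' @export
plot.hla_loh_call <- function(x, ...) print(autoplot(x, ...))

#' Plot the permutation background of an enrichment test
#'
#' Histogram of the simulated cohort loss proportions with the observed
#' proportion marked; the p-value is the mass at or right of the line.
#'
#' @param object A `loh_enrichment` from [simulate_loh_expectation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot loh_enrichment
#' @export
autoplot.loh_enrichment <- function(object, ...) {
  ggplot2::ggplot(tibble(prop = object$background),
                  ggplot2::aes(x = .data$prop)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "simulated cohort loss proportion", y = "replicates",
                  title = sprintf("Observed %.3f, p = %s", object$observed,
                                  format(object$p_floor))) +
    ggplot2::theme_minimal()
}

#' @export
plot.loh_enrichment <- function(x, ...) print(autoplot(x, ...))

#' Plot per-branch placement errors for an LOH event
#'
#' @param object A `loh_placement` from [map_loss_to_clone()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot loh_placement
#' @export
autoplot.loh_placement <- function(object, ...) {
  df <- object$by_branch %>%
    mutate(chosen = .data$clone == object$branch)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$clone, .data$error),
                                   y = .data$error, fill = .data$chosen)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "squared placement error",
                  title = sprintf("Event placed on %s%s", object$branch,
                                  if (object$unplaced) " (poor fit)" else "")) +
    ggplot2::theme_minimal()
}

#' @export
plot.loh_placement <- function(x, ...) print(autoplot(x, ...))
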