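# ggplot2 views of the main result tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-taxon amplification coverage
#'
#' Tile map of the fraction of records amplified, taxon by primer region.
#'
#' @param object A [coverage_by_rank()] table.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.coverage_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$region, y = .data$taxon, fill = .data$fraction
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d/%d", .data$n_amplified, .data$n_input)
    ), size = 3) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "steelblue4") +
    ggplot2::labs(x = "primer region", y = NULL,
                  fill = "fraction\namplified",
                  title = "In silico amplification coverage")
}

#' Plot re-classification outcomes per region and rank
#'
#' Stacked proportions of correct / mismatch / unclassified assignments.
#'
#' @param object A [score_reclassification()] report.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.reclassification_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::all_of(c("pct_correct", "pct_mismatch", "pct_unclassified")),
    names_to = "outcome", values_to = "pct", names_prefix = "pct_"
  )
  long$rank <- factor(long$rank, levels = RANKS)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$rank, y = .data$pct, fill = .data$outcome
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = NULL, y = "% of amplicons",
                  title = "Amplicon re-classification by rank") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot tree concordance per region
#'
#' Normalized Robinson-Foulds distance of each region tree to the
#' full-length tree (0 = identical topology).
#'
#' @param object A [region_concordance()] table.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.concordance_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$region, y = .data$rf_normalized
  )) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "primer region", y = "normalized RF vs full-length",
                  title = "Per-region tree concordance")
}
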