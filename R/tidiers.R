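# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a naive-Bayes classifier: one row per species
#'
#' @param x An `nb_classifier`.
#' @param ... Ignored.
#' @return A tibble of the training lineages.
#' @export
tidy.nb_classifier <- function(x, ...) {
  tibble::as_tibble(x$lineage)
}

#' One-row model summary for a naive-Bayes classifier
#'
#' @param x An `nb_classifier`.
#' @param ... Ignored.
#' @return A one-row tibble: `k`, `smoothing`, `n_species`, `n_training`,
#'   `vocabulary`.
#' @export
glance.nb_classifier <- function(x, ...) {
  tibble::tibble(
    k = x$k, smoothing = x$smoothing, n_species = length(x$species),
    n_training = x$n_training, vocabulary = 4^x$k
  )
}

#' One-row summary of a pipeline bundle
#'
#' @param x An `ampliregion_bundle`.
#' @param ... Ignored.
#' @return A one-row tibble of the headline numbers: mean coverage, mean
#'   species-level correct percentage, mean normalized RF, and the
#'   exclusion-correlation pair when computed.
#' @export
glance.ampliregion_bundle <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_species = nrow(x$db),
    mean_coverage = if (is.null(s$coverage_fraction)) NA_real_ else
      mean(unlist(s$coverage_fraction)),
    mean_species_pct_correct = if (is.null(s$species_pct_correct))
      NA_real_ else mean(unlist(s$species_pct_correct)),
    mean_rf_normalized = if (is.null(s$rf_normalized)) NA_real_ else
      mean(unlist(s$rf_normalized)),
    correlation_all_taxa = s$correlation_all_taxa %||% NA_real_,
    correlation_dominant_excluded =
      s$correlation_dominant_excluded %||% NA_real_
  )
}
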