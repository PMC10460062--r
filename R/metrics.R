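# Coverage tables, alpha diversity (Chao1, Shannon), rank-level relative
# abundance, detection overlap between primer schemes, and the
# dominant-taxon-exclusion correlation.

#' Amplification coverage grouped by a taxonomic rank
#'
#' Joins per-record amplification statuses with the reference taxonomy and
#' reports, per taxon at the requested rank, how many input records there
#' are and what fraction amplified (`status == "AMPLIFIED"`).
#'
#' @param statuses Status tibble from [run_insilico_pcr()] (or one region's
#'   slice of it); must cover every record it mentions once per region.
#' @param db Reference tibble with `record_id` and the 7 rank columns.
#' @param rank Rank name (`"phylum"`, `"genus"`, ...).
#' @param top_n Keep the `top_n` taxa by `n_input` and pool the remainder
#'   into an `"other"` row (default `Inf`: no pooling).
#' @return A tibble: `region`, `taxon`, `n_input`, `n_amplified`,
#'   `fraction`.
#' @export
coverage_by_rank <- function(statuses, db, rank = "phylum", top_n = Inf) {
  if (!rank %in% RANKS) {
    stop("unknown rank: ", rank, call. = FALSE)
  }
  missing <- setdiff(statuses$record_id, db$record_id)
  if (length(missing) > 0L) {
    stop("statuses mention records absent from the database: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  tab <- statuses |>
    dplyr::left_join(db[, c("record_id", rank)], by = "record_id") |>
    dplyr::rename(taxon = dplyr::all_of(rank)) |>
    dplyr::group_by(.data$region, .data$taxon) |>
    dplyr::summarise(
      n_input = dplyr::n(),
      n_amplified = sum(.data$status == "AMPLIFIED"),
      .groups = "drop"
    )
  if (is.finite(top_n)) {
    ranked <- tab |>
      dplyr::group_by(.data$taxon) |>
      dplyr::summarise(total = sum(.data$n_input)) |>
      dplyr::arrange(dplyr::desc(.data$total), .data$taxon)
    keep <- utils::head(ranked$taxon, top_n)
    tab <- tab |>
      dplyr::mutate(taxon = ifelse(.data$taxon %in% keep, .data$taxon,
                                   "other")) |>
      dplyr::group_by(.data$region, .data$taxon) |>
      dplyr::summarise(
        n_input = sum(.data$n_input),
        n_amplified = sum(.data$n_amplified),
        .groups = "drop"
      )
  }
  out <- tab |>
    dplyr::mutate(fraction = .data$n_amplified / .data$n_input) |>
    dplyr::arrange(.data$region, dplyr::desc(.data$n_input), .data$taxon)
  class(out) <- c("coverage_tbl", class(out))
  out
}

#' Chao1 richness estimator
#'
#' Bias-corrected form: `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1`
#' and `F2` are the numbers of species observed exactly once and twice.
#' Equals the observed richness whenever there are no singletons.
#'
#' @param counts Non-negative integer vector of per-species counts.
#' @return A single number; 0 (with a warning) for all-zero counts.
#' @examples
#' chao1(c(5, 5, 5)) # 3: no singletons
#' chao1(c(1, 1, 2, 3, 4)) # 5 + 2*1/4
#' @export
chao1 <- function(counts) {
  stopifnot(all(counts >= 0), all(counts == floor(counts)))
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    warning("all counts are zero; Chao1 undefined, returning 0")
    return(0)
  }
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' `H = -sum p_i log_base(p_i)` over species with positive counts,
#' `p_i = count_i / total`. Defaults to log base 2; use `base = exp(1)`
#' for nats.
#'
#' @param counts Non-negative numeric vector with at least one positive
#'   entry (counts or relative abundances).
#' @param base Logarithm base (default 2).
#' @return A single non-negative number.
#' @examples
#' shannon(c(1, 1, 1, 1)) # 2 bits
#' @export
shannon <- function(counts, base = 2) {
  stopifnot(all(counts >= 0))
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    stop("all counts are zero; Shannon index undefined", call. = FALSE)
  }
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Alpha-diversity summary per sample
#'
#' @param profile Long abundance/count tibble: `sample_id`, `taxon`,
#'   `abundance` (counts for Chao1; Shannon accepts either scale).
#' @param base Shannon log base (default 2).
#' @return A tibble per sample: `sample_id`, `observed`, `chao1`,
#'   `shannon`.
#' @export
alpha_diversity <- function(profile, base = 2) {
  profile |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      observed = sum(.data$abundance > 0),
      chao1 = chao1(.data$abundance),
      shannon = shannon(.data$abundance, base = base),
      .groups = "drop"
    )
}

#' Aggregate an abundance profile (or assignments) to a taxonomic rank
#'
#' Species-level abundances are summed up the lineage; assignments
#' truncated above the requested rank are pooled into
#' `"unassigned"`. Output abundances sum to 1 per sample.
#'
#' @param profile Long tibble `sample_id`, `taxon` (species label),
#'   `abundance`.
#' @param db Reference tibble mapping `species` to the higher ranks.
#' @param rank Target rank.
#' @return Long tibble `sample_id`, `taxon` (label at `rank`), `abundance`.
#' @export
relative_abundance <- function(profile, db, rank = "genus") {
  if (!rank %in% RANKS) stop("unknown rank: ", rank, call. = FALSE)
  lineage <- dplyr::distinct(db[, c("species", rank)])
  profile |>
    dplyr::left_join(lineage, by = c(taxon = "species")) |>
    dplyr::mutate(
      label = dplyr::coalesce(.data[[rank]], "unassigned")
    ) |>
    dplyr::group_by(.data$sample_id, taxon = .data$label) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(abundance = .data$abundance / sum(.data$abundance)) |>
    dplyr::ungroup()
}

#' Pearson correlation between two abundance profiles
#'
#' Profiles are aligned on the union of their taxa (absent taxa imputed 0);
#' `"unassigned"` entries are dropped. When `exclude` is given, that taxon
#' is removed from both profiles and each is renormalized to sum to one
#' before computing the correlation — the dominant-taxon-exclusion
#' analysis: when one abundant taxon is the sole source of disagreement
#' between two primer schemes, excluding it drives the correlation to 1.
#'
#' @param p1,p2 Tibbles with `taxon` and `abundance` columns (single
#'   profiles, e.g. sample-averaged).
#' @param exclude Optional taxon label to remove before correlating.
#' @return A list: `r` (Pearson correlation), `n_taxa`, `excluded`.
#' @export
profile_correlation <- function(p1, p2, exclude = NULL) {
  clean <- function(p) {
    p <- p[p$taxon != "unassigned", c("taxon", "abundance")]
    if (!is.null(exclude)) p <- p[p$taxon != exclude, ]
    stats::setNames(p$abundance / sum(p$abundance), p$taxon)
  }
  v1 <- clean(p1)
  v2 <- clean(p2)
  taxa <- sort(union(names(v1), names(v2)))
  if (length(taxa) < 3L) {
    stop("fewer than 3 taxa shared after alignment/exclusion",
         call. = FALSE)
  }
  x <- ifelse(is.na(v1[taxa]), 0, v1[taxa])
  y <- ifelse(is.na(v2[taxa]), 0, v2[taxa])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a profile; correlation undefined", call. = FALSE)
  }
  list(r = stats::cor(x, y), n_taxa = length(taxa),
       excluded = exclude %||% NA_character_)
}

#' Species-detection overlap between primer schemes
#'
#' Set algebra over the species detected by each scheme: per scheme the
#' number detected and the number detected by no other scheme, plus the
#' number shared by all schemes and the per-scheme count of assignments
#' left above species rank.
#'
#' @param detections Named list (one element per scheme) of character
#'   vectors of detected species labels.
#' @param unassigned Optional named integer vector: per-scheme count of
#'   taxa unassigned at species rank.
#' @return A tibble per scheme: `scheme`, `n_detected`, `n_exclusive`,
#'   `n_shared` (shared with at least one other scheme), `n_unassigned`;
#'   `n_detected = n_exclusive + n_shared`.
#' @examples
#' detection_comparison(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
#' @export
detection_comparison <- function(detections, unassigned = NULL) {
  stopifnot(length(detections) >= 2L, !is.null(names(detections)))
  detections <- lapply(detections, unique)
  schemes <- names(detections)
  rows <- lapply(schemes, function(s) {
    others <- unique(unlist(detections[setdiff(schemes, s)]))
    mine <- detections[[s]]
    tibble::tibble(
      scheme = s,
      n_detected = length(mine),
      n_exclusive = length(setdiff(mine, others)),
      n_shared = length(intersect(mine, others)),
      n_unassigned = if (is.null(unassigned)) NA_integer_ else
        as.integer(unassigned[[s]])
    )
  })
  dplyr::bind_rows(rows)
}
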