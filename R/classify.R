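# k-mer multinomial naive-Bayes taxonomy assignment with RDP-style bootstrap
# confidence, and reclassification-accuracy scoring of amplicons against
# their source records.

# base-4 k-mer indices (0-based) of a sequence; NULL if shorter than k
kmer_indices <- function(sequence, k) {
  b <- match(iupac_chars(sequence), c("A", "C", "G", "T")) - 1L
  n <- length(b)
  if (n < k) return(NULL)
  W <- n - k + 1L
  idx <- numeric(W)
  for (j in seq_len(k)) {
    idx <- idx * 4 + b[j:(j + W - 1L)]
  }
  idx
}

#' Train a k-mer multinomial naive-Bayes taxonomy classifier
#'
#' Per species, k-mer counts are pooled over its training sequences and
#' turned into smoothed multinomial log-probabilities:
#' `log((count + smoothing) / (total + smoothing * 4^k))`. Queries are
#' scored by the sum of log-probabilities over their k-mer multiset.
#'
#' @param db Training tibble with `sequence` and the 7 rank columns
#'   (`domain` ... `species`); several rows may share a species.
#' @param k k-mer length (>= 4; default 7, the common default of this
#'   classifier family).
#' @param smoothing Additive (Laplace) smoothing constant > 0.
#' @return An object of class `nb_classifier`.
#' @examples
#' db <- generate_reference_db(n_species = 6, seed = 1)
#' model <- train_nb(db, k = 7)
#' model
#' @export
train_nb <- function(db, k = 7L, smoothing = 1) {
  stopifnot(k >= 4L, smoothing > 0)
  too_short <- nchar(db$sequence) < k
  if (any(too_short)) {
    warning(sum(too_short), " training sequence(s) shorter than k excluded")
    db <- db[!too_short, ]
  }
  if (nrow(db) == 0L) stop("no training sequences of length >= k",
                           call. = FALSE)
  lineage <- dplyr::distinct(db[, RANKS])
  if (anyDuplicated(lineage$species)) {
    stop("a species maps to more than one lineage", call. = FALSE)
  }
  lineage <- dplyr::arrange(lineage, .data$species) # lexicographic tie order
  V <- 4^k
  counts <- matrix(0, nrow = nrow(lineage), ncol = V)
  for (i in seq_len(nrow(db))) {
    sp <- match(db$species[i], lineage$species)
    idx <- kmer_indices(db$sequence[i], k)
    counts[sp, ] <- counts[sp, ] + tabulate(idx + 1, nbins = V)
  }
  log_prob <- log(counts + smoothing) -
    log(rowSums(counts) + smoothing * V)
  structure(
    list(
      k = as.integer(k), smoothing = smoothing,
      species = lineage$species, lineage = lineage, log_prob = log_prob,
      n_training = nrow(db),
      fingerprint = sum(counts * seq_len(nrow(lineage))) %% 1e9
    ),
    class = "nb_classifier"
  )
}

#' @export
print.nb_classifier <- function(x, ...) {
  cat("k-mer naive-Bayes taxonomy classifier\n")
  cat("  k =", x$k, " smoothing =", x$smoothing, "\n")
  cat("  species:", length(x$species), " training sequences:",
      x$n_training, "\n")
  invisible(x)
}

# posterior log-scores of one query's k-mer count vector for every species
nb_scores <- function(model, uidx, ucnt) {
  as.vector(model$log_prob[, uidx + 1, drop = FALSE] %*% ucnt)
}

# smallest-label winner among scores tied with the maximum
argmax_lex <- function(scores, tol = 1e-9) {
  which(scores >= max(scores) - tol)[1L] # species are stored sorted
}

# random winner among tied scores (bootstrap replicates)
argmax_rand <- function(scores, tol = 1e-9) {
  tied <- which(scores >= max(scores) - tol)
  if (length(tied) == 1L) tied else tied[sample.int(length(tied), 1L)]
}

#' Assign taxonomy to query sequences with bootstrap confidence
#'
#' The point assignment is the species maximizing the smoothed multinomial
#' posterior over the query's k-mer multiset (ties broken by lexicographic
#' species label). Confidence at each rank is the fraction of bootstrap
#' replicates — each re-scoring a with-replacement resample of
#' `ceiling(m/8)` of the query's `m` k-mers — whose winning lineage agrees
#' with the point assignment at that rank; within replicates, score ties
#' are broken uniformly at random so that genuinely indistinguishable
#' species split the vote. The lineage is truncated at the deepest rank
#' whose confidence reaches `threshold`.
#'
#' @param queries Tibble with `query_id` and `sequence` columns.
#' @param model An [train_nb()] `nb_classifier`.
#' @param threshold Confidence threshold for rank truncation (default 0.7).
#' @param n_bootstrap Bootstrap replicates (default 100); `0` is a
#'   documented degenerate mode where every rank of the point assignment
#'   gets confidence 1.
#' @param seed Integer seed for the bootstrap resampling.
#' @return A tibble with one row per query: `query_id`, the 7 rank columns
#'   (NA below the truncation rank), `assigned_rank` (`"unclassified"` when
#'   even the domain fails the threshold or the query is shorter than k),
#'   `reason`, and 7 `conf_*` columns with per-rank confidences
#'   (non-increasing from domain to species).
#' @export
classify_sequences <- function(queries, model, threshold = 0.7,
                               n_bootstrap = 100L, seed = 1L) {
  stopifnot(inherits(model, "nb_classifier"))
  lin <- as.matrix(model$lineage)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(queries)), function(q) {
      out <- tibble::tibble(query_id = queries$query_id[q])
      idx <- kmer_indices(queries$sequence[q], model$k)
      if (is.null(idx)) {
        out[RANKS] <- NA_character_
        out$assigned_rank <- "unclassified"
        out$reason <- "shorter_than_k"
        out[paste0("conf_", RANKS)] <- 0
        return(out)
      }
      tab <- table(idx)
      uidx <- as.numeric(names(tab))
      ucnt <- as.vector(tab)
      point <- argmax_lex(nb_scores(model, uidx, ucnt))
      if (n_bootstrap > 0L) {
        m <- length(idx)
        size <- ceiling(m / 8)
        B <- stats::rmultinom(n_bootstrap, size, prob = ucnt / m)
        S <- model$log_prob[, uidx + 1, drop = FALSE] %*% B
        winners <- vapply(seq_len(n_bootstrap), function(b) {
          argmax_rand(S[, b])
        }, integer(1))
        conf <- vapply(seq_along(RANKS), function(r) {
          mean(lin[winners, r] == lin[point, r])
        }, numeric(1))
      } else {
        conf <- rep(1, 7L)
      }
      deepest <- max(c(0L, which(conf >= threshold)))
      assigned <- lin[point, ]
      if (deepest < 7L && deepest >= 0L) {
        assigned[seq.int(deepest + 1L, 7L)] <- NA_character_
      }
      out[RANKS] <- as.list(assigned)
      out$assigned_rank <- if (deepest == 0L) "unclassified" else
        RANKS[deepest]
      out$reason <- if (deepest == 0L) "low_confidence" else NA_character_
      out[paste0("conf_", RANKS)] <- as.list(conf)
      out
    })
    dplyr::bind_rows(rows)
  })
}

#' Score amplicon re-classification against source-record taxonomy
#'
#' Classifies each amplicon and compares the assignment with the lineage of
#' the record it was extracted from. At each rank an amplicon is *correct*
#' when the assigned label equals the source label, *unclassified* when the
#' assignment was truncated above that rank, and a *mismatch* otherwise;
#' the three counts sum to the number of amplicons at every rank.
#'
#' @param amplicons Tibble with `record_id`, `region`, `sequence`.
#' @param db Reference tibble carrying `record_id` and the 7 rank columns.
#' @param model An `nb_classifier` trained on `db` (or a superset).
#' @inheritParams classify_sequences
#' @return A tibble with one row per region x rank: `region`, `rank`,
#'   `n_correct`, `n_mismatch`, `n_unclassified`, `n`, and the matching
#'   percentages. Per-amplicon assignments are attached as attribute
#'   `"assignments"` (see [misclassification_by_genus()]).
#' @export
score_reclassification <- function(amplicons, db, model, threshold = 0.7,
                                   n_bootstrap = 100L, seed = 1L) {
  orphan <- setdiff(amplicons$record_id, db$record_id)
  if (length(orphan) > 0L) {
    stop("amplicons reference records absent from the database: ",
         paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
  }
  if (nrow(amplicons) == 0L) {
    return(tibble::tibble(
      region = character(0), rank = character(0), n_correct = integer(0),
      n_mismatch = integer(0), n_unclassified = integer(0), n = integer(0),
      pct_correct = numeric(0), pct_mismatch = numeric(0),
      pct_unclassified = numeric(0)
    ))
  }
  queries <- tibble::tibble(
    query_id = paste(amplicons$record_id, amplicons$region, sep = "|"),
    sequence = amplicons$sequence
  )
  asg <- classify_sequences(queries, model, threshold = threshold,
                            n_bootstrap = n_bootstrap, seed = seed)
  truth <- db[match(amplicons$record_id, db$record_id), RANKS]
  detail <- tibble::tibble(
    record_id = amplicons$record_id,
    region = amplicons$region,
    truth_genus = truth$genus,
    truth_species = truth$species
  )
  per_rank <- lapply(RANKS, function(r) {
    assigned <- asg[[r]]
    outcome <- dplyr::case_when(
      is.na(assigned) ~ "unclassified",
      assigned == truth[[r]] ~ "correct",
      TRUE ~ "mismatch"
    )
    tibble::tibble(region = amplicons$region, rank = r, outcome = outcome)
  })
  detail$species_outcome <- per_rank[[7]]$outcome
  report <- dplyr::bind_rows(per_rank) |>
    dplyr::count(.data$region, .data$rank, .data$outcome) |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "n",
                       values_fill = 0L)
  for (col in c("correct", "mismatch", "unclassified")) {
    if (!col %in% names(report)) report[[col]] <- 0L
  }
  report <- report |>
    dplyr::transmute(
      region = .data$region,
      rank = factor(.data$rank, levels = RANKS),
      n_correct = .data$correct,
      n_mismatch = .data$mismatch,
      n_unclassified = .data$unclassified,
      n = .data$correct + .data$mismatch + .data$unclassified,
      pct_correct = 100 * .data$n_correct / .data$n,
      pct_mismatch = 100 * .data$n_mismatch / .data$n,
      pct_unclassified = 100 * .data$n_unclassified / .data$n
    ) |>
    dplyr::arrange(.data$region, .data$rank) |>
    dplyr::mutate(rank = as.character(.data$rank))
  attr(report, "assignments") <- detail
  class(report) <- c("reclassification_report", class(report))
  report
}

#' Species-level misclassification counts by genus and region
#'
#' Tabulates, per source genus and primer region, how many amplicons were
#' mismatched or left unclassified at the species rank — the table behind
#' a genus x region misclassification heatmap.
#'
#' @param report A [score_reclassification()] result.
#' @return A tibble `genus` x `region` with `n_misclassified`.
#' @export
misclassification_by_genus <- function(report) {
  detail <- attr(report, "assignments")
  if (is.null(detail)) {
    stop("report carries no per-amplicon assignments", call. = FALSE)
  }
  detail |>
    dplyr::filter(.data$species_outcome != "correct") |>
    dplyr::count(genus = .data$truth_genus, region = .data$region,
                 name = "n_misclassified") |>
    tidyr::complete(.data$genus, .data$region,
                    fill = list(n_misclassified = 0L))
}
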