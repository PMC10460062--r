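# Distance matrices, neighbor-joining reconstruction and Robinson-Foulds
# concordance between per-region amplicon trees and the full-length tree.

#' Alignment-free k-mer Jaccard distance matrix
#'
#' `d(a, b) = 1 - |Ka intersect Kb| / |Ka union Kb|` over the sets of
#' distinct k-mers of each sequence — an alignment-free distance suited to
#' unaligned amplicons.
#'
#' @param seqs Tibble with a label column and a sequence column.
#' @param k k-mer length (default 8).
#' @param label_col,seq_col Column names (defaults `record_id`, `sequence`).
#' @return A symmetric numeric matrix with zero diagonal, labeled by
#'   `label_col`.
#' @examples
#' kmer_distance(tibble::tibble(record_id = c("a", "b"),
#'                              sequence = c("ACGTACGT", "ACGTACGA")), k = 4)
#' @export
kmer_distance <- function(seqs, k = 8L, label_col = "record_id",
                          seq_col = "sequence") {
  labels <- seqs[[label_col]]
  stopifnot(!anyDuplicated(labels))
  short <- nchar(seqs[[seq_col]]) < k
  if (any(short)) {
    stop("sequence(s) shorter than k: ",
         paste(labels[short], collapse = ", "), call. = FALSE)
  }
  sets <- lapply(seqs[[seq_col]], function(s) unique(kmer_indices(s, k)))
  n <- length(sets)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ni <- length(sets[[i]])
      nj <- length(sets[[j]])
      inter <- sum(sets[[i]] %in% sets[[j]])
      d[i, j] <- d[j, i] <- 1 - inter / (ni + nj - inter)
    }
  }
  d
}

#' Proportion-of-differing-sites distance from an alignment
#'
#' For each pair of rows of an equal-length alignment, the fraction of
#' mismatching columns among columns where neither sequence has a gap
#' (`-`). A pair with no comparable columns is an error.
#'
#' @param seqs Tibble of aligned sequences (see [kmer_distance()] for the
#'   column conventions); all sequences must have equal length.
#' @inheritParams kmer_distance
#' @return A symmetric numeric matrix with zero diagonal.
#' @examples
#' p_distance(tibble::tibble(record_id = c("a", "b"),
#'                           sequence = c("AC-T", "AG-T")))
#' @export
p_distance <- function(seqs, label_col = "record_id",
                       seq_col = "sequence") {
  labels <- seqs[[label_col]]
  stopifnot(!anyDuplicated(labels))
  lens <- nchar(seqs[[seq_col]])
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequences have unequal lengths", call. = FALSE)
  }
  chars <- lapply(seqs[[seq_col]], function(s) iupac_chars(s))
  n <- length(chars)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq.int(i + 1L, n)) {
      ok <- chars[[i]] != "-" & chars[[j]] != "-"
      if (!any(ok)) {
        stop("no comparable (gap-free) columns between ", labels[i],
             " and ", labels[j], call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(chars[[i]][ok] != chars[[j]][ok]) / sum(ok)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly joins the pair minimizing the
#' Q-criterion, assigns branch lengths by the two-point formulas, and
#' reduces the matrix, finishing with a trifurcating join of the last three
#' nodes (the tree is unrooted). Q-ties are broken by the smallest (i, j)
#' index pair, negative branch lengths are clamped to zero with the deficit
#' transferred to the sibling branch, so the reconstruction is exact on
#' additive matrices and deterministic everywhere.
#'
#' @param dm Symmetric distance matrix with unique dimnames and zero
#'   diagonal, from [kmer_distance()] or [p_distance()].
#' @return An unrooted `ape::phylo` tree whose tip labels are the matrix
#'   labels.
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-12 || any(diag(dm) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  labels <- rownames(dm)
  stopifnot(!is.null(labels), !anyDuplicated(labels))
  # each active node carries its newick sub-string
  reps <- labels
  D <- dm
  while (length(reps) > 3L) {
    r <- length(reps)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1L, ]
    i <- best[[1]]
    j <- best[[2]]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_rep <- sprintf("(%s:%.12g,%s:%.12g)", reps[i], li, reps[j], lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D[i, ] <- du
    D[, i] <- du
    D[i, i] <- 0
    keep <- setdiff(seq_len(r), j)
    D <- D[keep, keep, drop = FALSE]
    reps[i] <- new_rep
    reps <- reps[keep]
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                    reps[1], max(la, 0), reps[2], max(lb, 0),
                    reps[3], max(lc, 0))
  ape::read.tree(text = newick)
}

# canonical non-trivial bipartitions of an unrooted tree, each encoded as a
# sorted comma-joined label string of the side NOT containing the
# alphabetically first leaf
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  ref <- min(tree$tip.label)
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n))
  splits <- character(0)
  for (node in internal) {
    tips <- ape::extract.clade(tree, node)$tip.label
    if (ref %in% tips) tips <- setdiff(tree$tip.label, tips)
    if (length(tips) >= 2L && length(tips) <= n - 2L) {
      splits <- c(splits, paste(sort(tips), collapse = ","))
    }
  }
  unique(splits)
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the bipartitions (internal-edge splits) present in exactly one of
#' the two unrooted trees; branch lengths are ignored. The normalized form
#' divides by the maximum `2(n - 3)` for `n` shared leaves.
#'
#' @param t1,t2 `ape::phylo` trees on identical leaf sets.
#' @param normalized Return the normalized score in `[0, 1]`?
#' @return A single number.
#' @export
robinson_foulds <- function(t1, t2, normalized = FALSE) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets", call. = FALSE)
  }
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  rf <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (normalized) {
    n <- length(t1$tip.label)
    if (n <= 3L) return(0)
    rf / (2 * (n - 3))
  } else {
    rf
  }
}

#' Per-region tree concordance with the full-length tree
#'
#' Runs in silico PCR for the panel, builds a neighbor-joining tree from
#' each region's amplicons and from the full-length sequences of the same
#' records (k-mer Jaccard distance), and scores each region tree against
#' the full-length tree by Robinson-Foulds distance. Records not amplified
#' by every region are dropped (with a message) so all trees share one leaf
#' set.
#'
#' @param db Reference tibble (`record_id`, `sequence`, rank columns).
#' @param panel Primer panel tibble.
#' @param k k-mer length for the distance (default 8).
#' @param max_mismatch,mode Passed to [run_insilico_pcr()].
#' @param taxa Optional character vector of species labels to restrict the
#'   analysis to (e.g. a periodontal-pathogen panel).
#' @return A tibble with one row per region: `region`, `n_taxa`, `rf`,
#'   `rf_normalized`, plus a `full_tree` / `region_trees` attribute pair
#'   holding the `phylo` objects.
#' @export
region_concordance <- function(db, panel, k = 8L, max_mismatch = 0L,
                               mode = "included", taxa = NULL) {
  if (!is.null(taxa)) {
    db <- db[db$species %in% taxa, ]
    if (nrow(db) == 0L) stop("taxa filter matches no records", call. = FALSE)
  }
  res <- run_insilico_pcr(db, panel, max_mismatch = max_mismatch,
                          mode = mode)
  amp <- res$amplicons
  common <- Reduce(intersect, split(amp$record_id, amp$region))
  dropped <- setdiff(db$record_id, common)
  if (length(dropped) > 0L) {
    message(length(dropped), " record(s) not amplified by every region ",
            "dropped from concordance: ",
            paste(utils::head(dropped, 10L), collapse = ", "))
  }
  if (length(common) < 4L) {
    stop("fewer than 4 records amplified by every region", call. = FALSE)
  }
  common <- sort(common)
  full_tree <- neighbor_joining(
    kmer_distance(db[match(common, db$record_id), ], k = k)
  )
  regions <- unique(panel$region)
  region_trees <- list()
  rows <- lapply(regions, function(rg) {
    a <- amp[amp$region == rg & amp$record_id %in% common, ]
    a <- a[match(common, a$record_id), ]
    tr <- neighbor_joining(kmer_distance(a, k = k))
    region_trees[[rg]] <<- tr
    tibble::tibble(
      region = rg,
      n_taxa = length(common),
      rf = robinson_foulds(full_tree, tr),
      rf_normalized = robinson_foulds(full_tree, tr, normalized = TRUE)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "full_tree") <- full_tree
  attr(out, "region_trees") <- region_trees
  class(out) <- c("concordance_tbl", class(out))
  out
}
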