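# Synthetic 16S-like reference databases: conserved blocks interleaved with
# variable regions, a clade-hierarchical mutation process down a 7-rank
# taxonomy, planted degenerate-primer sites with controllable dropout, and
# log-normal community profiles. Stands in for a curated full-length 16S
# reference set so the whole pipeline is testable offline.

RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

# Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Describe the conserved/variable architecture of a synthetic 16S-like gene
#'
#' The real 16S rRNA gene is ~1.5 kb with nine variable regions (V1-V9)
#' interleaved among highly conserved blocks; the layout mirrors that scale:
#' ten conserved blocks C0..C9 flanking nine variable regions V1..V9.
#' Per-region `conservation` is the probability that a base is shared across
#' clades rather than free to diverge (1 = frozen, 0 = fully free); it scales
#' the per-rank substitution rates of [generate_reference_db()].
#'
#' @param conserved_length,variable_length Block lengths in bp.
#' @param conserved_conservation,variable_conservation Default conservation
#'   levels in `[0, 1]` for the two block classes.
#' @param conservation_override Optional named numeric vector overriding the
#'   conservation of specific regions, e.g. `c(V3 = 1, V4 = 1)` to erase all
#'   divergence signal from V3 and V4.
#' @return A tibble with columns `region`, `length`, `conservation`, `start`,
#'   `end` (0-based, half-open coordinates of each block).
#' @examples
#' region_layout()
#' region_layout(conservation_override = c(V1 = 0, V2 = 0, V3 = 1))
#' @export
region_layout <- function(conserved_length = 65, variable_length = 90,
                          conserved_conservation = 0.95,
                          variable_conservation = 0.25,
                          conservation_override = NULL) {
  regions <- c(rbind(paste0("C", 0:8), paste0("V", 1:9)), "C9")
  is_var <- grepl("^V", regions)
  layout <- tibble::tibble(
    region = regions,
    length = ifelse(is_var, variable_length, conserved_length),
    conservation = ifelse(is_var, variable_conservation,
                          conserved_conservation)
  )
  if (!is.null(conservation_override)) {
    bad <- setdiff(names(conservation_override), layout$region)
    if (length(bad) > 0L) {
      stop("unknown regions in conservation_override: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    layout$conservation[match(names(conservation_override), layout$region)] <-
      unname(conservation_override)
  }
  if (any(layout$length < 1) ||
      any(layout$conservation < 0 | layout$conservation > 1)) {
    stop("region lengths must be >= 1 and conservation within [0, 1]",
         call. = FALSE)
  }
  layout$start <- cumsum(c(0L, layout$length[-nrow(layout)]))
  layout$end <- layout$start + layout$length
  layout
}

# Default 7-rank group counts for n species: a handful of phyla fanning out
# to one record per species.
default_taxonomy_shape <- function(n_species) {
  shape <- c(
    domain = 1L,
    phylum = max(2L, ceiling(n_species / 40)),
    class = ceiling(n_species / 25),
    order = ceiling(n_species / 15),
    family = ceiling(n_species / 8),
    genus = ceiling(n_species / 3),
    species = n_species
  )
  as.integer(cummax(shape))
}

#' Generate a taxonomy-labeled synthetic 16S-like reference database
#'
#' Draws one root sequence, then mutates it down a nested 7-rank taxonomy:
#' each clade at each rank inherits its parent clade's sequence with
#' per-position substitution probability `rank_rate * (1 - conservation)`.
#' Variable regions therefore accumulate clade-private substitutions while
#' conserved blocks stay near-identical, so records sharing a genus are more
#' similar than records from different phyla, by construction.
#'
#' @param n_species Number of species (= records; one record per species).
#' @param taxonomy_shape Integer vector of 7 group counts, domain to species,
#'   non-decreasing, ending at `n_species`. Default derives a plausible
#'   fan-out from `n_species`.
#' @param layout A [region_layout()] tibble.
#' @param seed Integer seed; the generator is a pure function of its seed
#'   and parameters.
#' @param rank_rates Per-rank substitution probabilities applied at each
#'   inheritance step (phylum through species).
#' @return A tibble with columns `record_id`, `sequence` and the 7 rank
#'   labels, with the layout attached as attribute `"layout"`.
#' @examples
#' db <- generate_reference_db(n_species = 10, seed = 1)
#' dplyr::count(db, phylum)
#' @export
generate_reference_db <- function(n_species,
                                  taxonomy_shape = NULL,
                                  layout = region_layout(),
                                  seed = 1L,
                                  rank_rates = c(
                                    phylum = 0.14, class = 0.10,
                                    order = 0.08, family = 0.06,
                                    genus = 0.05, species = 0.04
                                  )) {
  stopifnot(n_species >= 2L)
  if (is.null(taxonomy_shape)) {
    taxonomy_shape <- default_taxonomy_shape(n_species)
  }
  taxonomy_shape <- as.integer(taxonomy_shape)
  if (length(taxonomy_shape) != 7L || is.unsorted(taxonomy_shape) ||
      taxonomy_shape[1] < 1L || taxonomy_shape[7] != n_species) {
    stop("taxonomy_shape must be 7 non-decreasing group counts ending at ",
         "n_species", call. = FALSE)
  }

  # nested group membership: group j at rank r descends from
  # ceiling(j * n_groups[r-1] / n_groups[r]) at rank r-1
  parent_of <- function(j, n_parent, n_child) ceiling(j * n_parent / n_child)
  groups <- vector("list", 7L)
  groups[[7]] <- seq_len(n_species)
  for (r in 6:1) {
    groups[[r]] <- parent_of(groups[[r + 1]], taxonomy_shape[r],
                             taxonomy_shape[r + 1])
  }

  n_pos <- sum(layout$length)
  free <- rep(1 - layout$conservation, layout$length)
  bases <- c("A", "C", "G", "T")

  with_seed(seed, {
    root <- sample(bases, n_pos, replace = TRUE)
    seqs_by_rank <- list(list(root)) # rank 1 (domain), single group
    for (r in 2:7) {
      rate <- rank_rates[[RANKS[r]]]
      n_groups <- taxonomy_shape[r]
      parent_groups <- parent_of(seq_len(n_groups), taxonomy_shape[r - 1],
                                 n_groups)
      seqs <- vector("list", n_groups)
      for (g in seq_len(n_groups)) {
        s <- seqs_by_rank[[r - 1]][[parent_groups[g]]]
        hit <- which(stats::runif(n_pos) < rate * free)
        if (length(hit) > 0L) {
          # substitute to one of the three other bases
          s[hit] <- vapply(s[hit], function(b) {
            sample(setdiff(bases, b), 1L)
          }, character(1))
        }
        seqs[[g]] <- s
      }
      seqs_by_rank[[r]] <- seqs
    }
    label <- function(prefix, idx) sprintf("%s%03d", prefix, idx)
    db <- tibble::tibble(
      record_id = sprintf("R%04d", seq_len(n_species)),
      sequence = vapply(seqs_by_rank[[7]], paste, character(1), collapse = ""),
      domain = "Bacteria",
      phylum = label("P", groups[[2]]),
      class = label("C", groups[[3]]),
      order = label("O", groups[[4]]),
      family = label("F", groups[[5]]),
      genus = label("G", groups[[6]]),
      species = label("S", groups[[7]])
    )
    attr(db, "layout") <- layout
    db
  })
}

#' Declare per-clade primer-site dropout
#'
#' A dropout row removes or degrades one primer's binding site in a fraction
#' of the records of one clade, creating ground-truth differential coverage
#' (the mechanism by which real primer pairs miss whole phyla).
#'
#' @param primer Primer-pair region name (matches the panel's `region`).
#' @param site `"forward"` or `"reverse"`.
#' @param rank Taxonomic rank of the selector (e.g. `"phylum"`).
#' @param taxon Clade label at that rank.
#' @param fraction Fraction of the clade's records to perturb, in `[0, 1]`;
#'   `floor(fraction * n)` records are selected after a seeded shuffle.
#' @param perturbation `"delete"` (excise the site) or `"mutate"` (plant
#'   `k` primer-incompatible bases inside it).
#' @param k Number of mutated bases when `perturbation = "mutate"`.
#' @return A one-row tibble; rows from several calls can be
#'   `dplyr::bind_rows()`-ed into a dropout table.
#' @export
dropout_spec <- function(primer, site = c("forward", "reverse"),
                         rank = "phylum", taxon, fraction,
                         perturbation = c("delete", "mutate"), k = 1L) {
  site <- match.arg(site)
  perturbation <- match.arg(perturbation)
  stopifnot(fraction >= 0, fraction <= 1, k >= 1L, rank %in% RANKS)
  tibble::tibble(
    primer = primer, site = site, rank = rank, taxon = taxon,
    fraction = fraction, perturbation = perturbation, k = as.integer(k)
  )
}

# "V1-V2" / "V1–V2" -> c(3, 5) (indices of first and last variable
# region covered)
parse_region_span <- function(region) {
  m <- regmatches(region, gregexpr("V([0-9])", region))[[1]]
  if (length(m) < 1L) {
    stop("cannot parse variable-region span from region name: ", region,
         call. = FALSE)
  }
  v <- as.integer(sub("V", "", m))
  c(first = min(v), last = max(v))
}

#' Plant exact primer-binding sites into a synthetic reference database
#'
#' Each primer pair named `"Vi-Vj"` gets its forward site written into the
#' conserved block upstream of Vi (right-aligned) and the reverse-complement
#' of its reverse primer into the conserved block downstream of Vj
#' (left-aligned); one concrete realization of each degenerate primer is
#' drawn per site and shared by all records. Sites of several primers
#' sharing a conserved block are stacked without overlap. Records selected
#' by `dropout` then have the named site deleted or mutated.
#'
#' @param db A [generate_reference_db()] tibble.
#' @param panel Primer panel tibble (`region`, `forward`, `reverse`).
#' @param layout The layout used to build `db` (default: its attribute).
#' @param dropout Optional dropout table from [dropout_spec()] rows.
#' @param seed Integer seed for realization draws, dropout shuffles and
#'   mutation placement.
#' @return A list: `db` (modified tibble) and `ground_truth`, a tibble with
#'   one row per record x primer x site: `record_id`, `primer`, `site`,
#'   `start`, `end` (current coordinates; `NA` for deleted sites), `status`
#'   (`PRESENT`/`ABSENT`) and `perturbation` (`none`/`delete`/`mutate`).
#'   `ABSENT` sites do not match their primer exactly; `PRESENT` sites do.
#' @export
plant_primer_sites <- function(db, panel, layout = attr(db, "layout"),
                               dropout = NULL, seed = 1L) {
  if (is.null(layout)) {
    stop("no layout: pass the layout used to generate the database",
         call. = FALSE)
  }
  conserved <- layout[grepl("^C", layout$region), ]
  n_pos <- sum(layout$length)
  with_seed(seed, {
    # site skeleton: block assignment and stacking (forward sites
    # right-aligned against the next variable region, reverse sites
    # left-aligned), independent of the realizations drawn below
    sites <- dplyr::bind_rows(lapply(seq_len(nrow(panel)), function(p) {
      span <- parse_region_span(panel$region[p])
      tibble::tibble(
        primer = panel$region[p],
        site = c("forward", "reverse"),
        pattern = c(panel$forward[p],
                    reverse_complement(panel$reverse[p])),
        block = paste0("C", c(span[["first"]] - 1L, span[["last"]]))
      )
    }))
    if (!all(sites$block %in% conserved$region)) {
      stop("primer span outside the layout's variable regions",
           call. = FALSE)
    }
    sites$width <- nchar(sites$pattern)
    sites$start <- NA_integer_
    for (b in unique(sites$block)) {
      blk <- conserved[conserved$region == b, ]
      rows_f <- which(sites$block == b & sites$site == "forward")
      rows_r <- which(sites$block == b & sites$site == "reverse")
      off <- blk$end
      for (i in rows_f) {
        off <- off - sites$width[i]
        sites$start[i] <- off
      }
      off_l <- blk$start
      for (i in rows_r) {
        sites$start[i] <- off_l
        off_l <- off_l + sites$width[i]
      }
      if (off < off_l) {
        stop("conserved block ", b, " is too short for its primer sites ",
             "(need ", blk$length + (off_l - off), " bp, have ", blk$length,
             ")", call. = FALSE)
      }
    }
    sites$end <- sites$start + sites$width

    # Draw one concrete realization per site such that no primer pattern
    # matches anywhere except its own site. Several 16S primers share
    # conserved motifs (e.g. the V4-V5 forward site contains the reverse
    # complement of the V1-V3 reverse primer), so a candidate draw is
    # planted into every record and verified with the matcher; draws are
    # repeated until each pattern has exactly one exact hit per record.
    masks <- lapply(sites$pattern, iupac_mask)
    in_site <- rep(FALSE, n_pos)
    for (i in seq_len(nrow(sites))) {
      in_site[(sites$start[i] + 1L):sites$end[i]] <- TRUE
    }
    bases <- c("A", "C", "G", "T")
    ok <- FALSE
    for (attempt in 1:50) {
      sites$planted <- vapply(sites$pattern, function(p) {
        sample(iupac_expand(p), 1L)
      }, character(1), USE.NAMES = FALSE)
      seqs_try <- db$sequence
      for (i in seq_len(nrow(sites))) {
        substr(seqs_try, sites$start[i] + 1L, sites$end[i]) <-
          sites$planted[i]
      }
      # Off-target windows that extend outside the planted sites are broken
      # by switching one free template base to a primer-incompatible one;
      # windows lying fully inside planted sites can only be fixed by
      # drawing different realizations.
      redraw <- FALSE
      for (pass in 1:10) {
        clean <- TRUE
        for (r in seq_along(seqs_try)) {
          bits <- encode_bases(seqs_try[r])
          for (i in seq_along(masks)) {
            L <- length(masks[[i]])
            hits <- which(window_mismatches(bits, masks[[i]]) == 0L) - 1L
            codes <- iupac_chars(sites$pattern[i])
            for (o in setdiff(hits, sites$start[i])) {
              free <- which(!in_site[(o + 1L):(o + L)] &
                              lengths(.IUPAC_SETS[codes]) < 4L)
              if (length(free) == 0L) {
                redraw <- TRUE
                break
              }
              clean <- FALSE
              pos <- o + free[1L]
              bad <- setdiff(bases, .IUPAC_SETS[[codes[free[1L]]]])
              substr(seqs_try[r], pos, pos) <- bad[1L]
            }
            if (redraw) break
          }
          if (redraw) break
        }
        if (redraw || clean) break
      }
      if (!redraw && clean) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not plant cross-match-free primer sites for this ",
           "panel/layout", call. = FALSE)
    }
    db$sequence <- seqs_try

    seqs <- db$sequence

    gt <- tidyr::crossing(
      tibble::tibble(record_id = db$record_id),
      sites[, c("primer", "site", "start", "end")]
    )
    gt$status <- "PRESENT"
    gt$perturbation <- "none"

    if (!is.null(dropout) && nrow(dropout) > 0L) {
      for (d in seq_len(nrow(dropout))) {
        sel <- which(db[[dropout$rank[d]]] == dropout$taxon[d])
        n_hit <- floor(dropout$fraction[d] * length(sel))
        hit <- sel[sample.int(length(sel))][seq_len(n_hit)]
        srow <- sites[sites$primer == dropout$primer[d] &
                        sites$site == dropout$site[d], ]
        if (nrow(srow) != 1L) {
          stop("dropout names an unplanted primer/site: ",
               dropout$primer[d], " ", dropout$site[d], call. = FALSE)
        }
        for (r in hit) {
          g <- which(gt$record_id == db$record_id[r] &
                       gt$primer == dropout$primer[d] &
                       gt$site == dropout$site[d])
          s0 <- gt$start[g]
          e0 <- gt$end[g]
          if (is.na(s0) || gt$status[g] == "ABSENT") next
          if (dropout$perturbation[d] == "delete") {
            seqs[r] <- paste0(substr(seqs[r], 1L, s0),
                              substr(seqs[r], e0 + 1L, nchar(seqs[r])))
            # shift this record's downstream sites
            rec_rows <- which(gt$record_id == db$record_id[r] &
                                !is.na(gt$start) & gt$start >= e0)
            gt$start[rec_rows] <- gt$start[rec_rows] - (e0 - s0)
            gt$end[rec_rows] <- gt$end[rec_rows] - (e0 - s0)
            gt$start[g] <- NA_integer_
            gt$end[g] <- NA_integer_
            gt$status[g] <- "ABSENT"
            gt$perturbation[g] <- "delete"
          } else {
            # mutate k bases to primer-incompatible ones; positions must
            # carry a code excluding at least one base
            pat <- if (dropout$site[d] == "forward") {
              panel$forward[panel$region == dropout$primer[d]]
            } else {
              reverse_complement(panel$reverse[panel$region ==
                                                 dropout$primer[d]])
            }
            codes <- iupac_chars(pat)
            eligible <- which(lengths(.IUPAC_SETS[codes]) < 4L)
            if (length(eligible) < dropout$k[d]) {
              stop("primer ", dropout$primer[d], " has fewer than k ",
                   "non-degenerate positions to mutate", call. = FALSE)
            }
            pos <- sort(eligible[sample.int(length(eligible))][
              seq_len(dropout$k[d])])
            for (p0 in pos) {
              allowed <- setdiff(c("A", "C", "G", "T"),
                                 .IUPAC_SETS[[codes[p0]]])
              sub <- if (length(allowed) == 1L) allowed else
                sample(allowed, 1L)
              substr(seqs[r], s0 + p0, s0 + p0) <- sub
            }
            gt$status[g] <- "ABSENT"
            gt$perturbation[g] <- "mutate"
          }
        }
      }
    }
    db$sequence <- seqs
    attr(db, "layout") <- layout
    list(db = db, ground_truth = gt)
  })
}

#' Simulate log-normal community abundance profiles over a reference set
#'
#' Species abundances are drawn i.i.d. log-normal and normalized to sum to
#' one per sample. An optional dominant genus is pinned to a target share:
#' its species are rescaled to sum to the target and the remainder is
#' renormalized to `1 - target` — emulating communities in which one genus
#' (e.g. *Streptococcus* in the oral cavity) dwarfs the rest.
#'
#' @param db Reference tibble with `species` and `genus` columns.
#' @param n_samples Number of independent profiles.
#' @param mu,sigma Log-normal parameters (`sigma >= 0`; `sigma = 0` gives
#'   equal abundances).
#' @param dominant Optional `list(genus =, share =)` with share in (0, 1).
#' @param seed Integer seed.
#' @return A long tibble: `sample_id`, `taxon` (species label), `abundance`;
#'   abundances sum to 1 per sample within 1e-9.
#' @examples
#' db <- generate_reference_db(n_species = 12, seed = 1)
#' generate_community(db, n_samples = 2,
#'                    dominant = list(genus = db$genus[1], share = 0.5),
#'                    seed = 7)
#' @export
generate_community <- function(db, n_samples = 1L, mu = 0, sigma = 1,
                               dominant = NULL, seed = 1L) {
  if (nrow(db) == 0L) stop("empty reference database", call. = FALSE)
  stopifnot(sigma >= 0, n_samples >= 1L)
  if (!is.null(dominant)) {
    stopifnot(dominant$share > 0, dominant$share < 1)
    if (!any(db$genus == dominant$genus)) {
      stop("dominant genus not present in the database: ", dominant$genus,
           call. = FALSE)
    }
    if (all(db$genus == dominant$genus)) {
      stop("dominant genus covers the whole database; no remainder to ",
           "renormalize", call. = FALSE)
    }
  }
  n <- nrow(db)
  with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_samples), function(s) {
      x <- stats::rlnorm(n, meanlog = mu, sdlog = sigma)
      p <- x / sum(x)
      if (!is.null(dominant)) {
        in_g <- db$genus == dominant$genus
        p[in_g] <- p[in_g] / sum(p[in_g]) * dominant$share
        p[!in_g] <- p[!in_g] / sum(p[!in_g]) * (1 - dominant$share)
      }
      tibble::tibble(
        sample_id = sprintf("SAMPLE%02d", s),
        taxon = db$species,
        abundance = p
      )
    }))
  })
}
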