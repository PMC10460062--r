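# In silico PCR: degenerate-primer site matching and amplicon extraction.
# A primer matches a window when every sequence base lies inside the IUPAC
# set of the corresponding primer code; mismatches are incompatible positions.
# All coordinates are 0-based, half-open, on the forward strand.

# Mismatch count of `mask` against every window of `seq_bits`.
window_mismatches <- function(seq_bits, mask) {
  L <- length(mask)
  n <- length(seq_bits)
  if (L > n) return(integer(0))
  W <- n - L + 1L
  mm <- integer(W)
  for (j in seq_len(L)) {
    mm <- mm + (bitwAnd(seq_bits[j:(j + W - 1L)], mask[j]) == 0L)
  }
  mm
}

#' Locate degenerate-primer binding sites on a reference sequence
#'
#' Scans the forward strand of `sequence` for windows compatible with the
#' IUPAC primer. In `"forward"` orientation the primer itself is matched; in
#' `"reverse"` orientation the reverse complement of the primer is matched
#' (the site a reverse primer binds on the template's forward strand).
#'
#' @param sequence A single reference sequence over `{A,C,G,T}`.
#' @param primer An IUPAC primer string.
#' @param orientation `"forward"` or `"reverse"`.
#' @param max_mismatch Maximum number of incompatible positions (default 0).
#' @return A tibble with one row per hit, sorted by `start`: columns
#'   `start`, `end` (0-based, half-open), `strand` (`"+"` for forward,
#'   `"-"` for reverse sites) and `mismatch`. A primer longer than the
#'   sequence yields zero rows.
#' @examples
#' find_primer_sites(paste0(strrep("A", 30), "CCTACGGGAGGCTGCAG"),
#'                   "CCTACGGGNGGCWGCAG")
#' @export
find_primer_sites <- function(sequence, primer,
                              orientation = c("forward", "reverse"),
                              max_mismatch = 0L) {
  orientation <- match.arg(orientation)
  stopifnot(length(sequence) == 1L, length(primer) == 1L, max_mismatch >= 0L)
  pat <- if (orientation == "forward") primer else reverse_complement(primer)
  mask <- iupac_mask(pat)
  mm <- window_mismatches(encode_bases(sequence), mask)
  keep <- which(mm <= max_mismatch)
  tibble::tibble(
    start = keep - 1L,
    end = keep - 1L + length(mask),
    strand = if (orientation == "forward") "+" else "-",
    mismatch = as.integer(mm[keep])
  )
}

#' Extract the amplicon delimited by a forward and a reverse primer hit
#'
#' In `"included"` mode the amplicon spans both primer sites,
#' `[forward_hit$start, reverse_hit$end)` — what a sequencer would read. In
#' `"excluded"` mode it is the inter-primer insert,
#' `[forward_hit$end, reverse_hit$start)`.
#'
#' @param sequence The reference sequence the hits were found on.
#' @param forward_hit,reverse_hit One-row data frames with `start`/`end`
#'   columns, as returned by [find_primer_sites()].
#' @param mode `"included"` or `"excluded"`.
#' @return A one-row tibble with `start`, `end`, `sequence`, `mode` and
#'   `degenerate` (`TRUE` for a zero-length insert). Inverted or overlapping
#'   hits (forward site not strictly upstream of the reverse site) give a
#'   zero-row tibble: no amplicon.
#' @export
extract_amplicon <- function(sequence, forward_hit, reverse_hit,
                             mode = c("included", "excluded")) {
  mode <- match.arg(mode)
  empty <- tibble::tibble(
    start = integer(0), end = integer(0), sequence = character(0),
    mode = character(0), degenerate = logical(0)
  )
  if (nrow(forward_hit) != 1L || nrow(reverse_hit) != 1L) return(empty)
  if (forward_hit$end > reverse_hit$start) return(empty)
  if (mode == "included") {
    s <- forward_hit$start
    e <- reverse_hit$end
  } else {
    s <- forward_hit$end
    e <- reverse_hit$start
  }
  tibble::tibble(
    start = as.integer(s),
    end = as.integer(e),
    sequence = substr(sequence, s + 1L, e),
    mode = mode,
    degenerate = e == s
  )
}

#' Run in silico PCR for a primer panel over a reference database
#'
#' For every record and every primer pair, locates forward and reverse
#' binding sites, pairs them (forward site strictly upstream of the reverse
#' site, spanned product within `product_size_bounds`), and extracts one
#' amplicon per amplifiable record. When several (forward, reverse) pairings
#' pass the size bounds the shortest product is emitted and the record is
#' flagged `MULTIPLE_PRODUCTS`.
#'
#' @param db Reference tibble with columns `record_id` and `sequence`
#'   (taxonomy columns are carried along untouched).
#' @param panel Primer panel tibble with columns `region`, `forward`,
#'   `reverse` (see [default_primer_panel()]).
#' @param max_mismatch Maximum mismatches per primer site (default 0:
#'   exact degenerate matching).
#' @param mode Amplicon mode passed to [extract_amplicon()]; default
#'   `"included"`.
#' @param product_size_bounds Length-2 numeric: allowed spanned-product
#'   (primer-to-primer, inclusive of sites) size range in bp.
#' @return A list with two tibbles: `amplicons` (`record_id`, `region`,
#'   `start`, `end`, `sequence`, `mode`, `degenerate`) and `statuses`
#'   (`record_id`, `region`, `status`), one status per record x region with
#'   `status` in `AMPLIFIED`, `NO_FORWARD`, `NO_REVERSE`, `NO_SITE`,
#'   `MULTIPLE_PRODUCTS`.
#' @examples
#' db <- generate_reference_db(n_species = 5, seed = 1)
#' planted <- plant_primer_sites(db, default_primer_panel(), seed = 2)
#' res <- run_insilico_pcr(planted$db, default_primer_panel())
#' dplyr::count(res$statuses, region, status)
#' @export
run_insilico_pcr <- function(db, panel, max_mismatch = 0L,
                             mode = c("included", "excluded"),
                             product_size_bounds = c(50, 2000)) {
  mode <- match.arg(mode)
  stopifnot(nrow(db) > 0L, nrow(panel) > 0L, length(product_size_bounds) == 2L)
  fwd_masks <- lapply(panel$forward, iupac_mask)
  rev_masks <- lapply(reverse_complement(panel$reverse), iupac_mask)

  status_rows <- vector("list", nrow(db) * nrow(panel))
  amp_rows <- vector("list", nrow(db) * nrow(panel))
  idx <- 0L
  for (i in seq_len(nrow(db))) {
    seq_i <- db$sequence[i]
    bits <- encode_bases(seq_i)
    for (p in seq_len(nrow(panel))) {
      idx <- idx + 1L
      fmm <- window_mismatches(bits, fwd_masks[[p]])
      rmm <- window_mismatches(bits, rev_masks[[p]])
      fpos <- which(fmm <= max_mismatch)
      rpos <- which(rmm <= max_mismatch)
      status <- if (length(fpos) == 0L && length(rpos) == 0L) {
        "NO_SITE"
      } else if (length(fpos) == 0L) {
        "NO_FORWARD"
      } else if (length(rpos) == 0L) {
        "NO_REVERSE"
      } else {
        NA_character_
      }
      if (is.na(status)) {
        flen <- length(fwd_masks[[p]])
        rlen <- length(rev_masks[[p]])
        # all orientation-consistent pairings within size bounds
        pairs <- expand.grid(f = fpos, r = rpos)
        f_end <- pairs$f - 1L + flen
        r_start <- pairs$r - 1L
        span <- r_start + rlen - (pairs$f - 1L)
        ok <- f_end <= r_start &
          span >= product_size_bounds[1] & span <= product_size_bounds[2]
        pairs <- pairs[ok, , drop = FALSE]
        span <- span[ok]
        if (nrow(pairs) == 0L) {
          status <- "NO_SITE"
        } else {
          status <- if (nrow(pairs) == 1L) "AMPLIFIED" else "MULTIPLE_PRODUCTS"
          best <- order(span, pairs$f, pairs$r)[1L]
          fh <- tibble::tibble(
            start = pairs$f[best] - 1L,
            end = pairs$f[best] - 1L + flen
          )
          rh <- tibble::tibble(
            start = pairs$r[best] - 1L,
            end = pairs$r[best] - 1L + rlen
          )
          amp <- extract_amplicon(seq_i, fh, rh, mode)
          if (nrow(amp) == 1L) {
            amp_rows[[idx]] <- dplyr::bind_cols(
              tibble::tibble(
                record_id = db$record_id[i],
                region = panel$region[p]
              ),
              amp
            )
          }
        }
      }
      status_rows[[idx]] <- tibble::tibble(
        record_id = db$record_id[i],
        region = panel$region[p],
        status = status
      )
    }
  }
  amplicons <- dplyr::bind_rows(amp_rows)
  if (nrow(amplicons) == 0L) {
    amplicons <- tibble::tibble(
      record_id = character(0), region = character(0), start = integer(0),
      end = integer(0), sequence = character(0), mode = character(0),
      degenerate = logical(0)
    )
  }
  list(amplicons = amplicons, statuses = dplyr::bind_rows(status_rows))
}
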