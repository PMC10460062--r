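# File formats: FASTA via Biostrings, QIIME-style lineage TSV, primer-panel
# TSV, ground-truth TSV. Writes are atomic (temp file then rename) and each
# pipeline output can carry a config-hash header comment.

LINEAGE_PREFIXES <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")

lineage_string <- function(db_row) {
  paste0(LINEAGE_PREFIXES, unlist(db_row[RANKS]), collapse = "; ")
}

parse_lineage <- function(x) {
  parts <- strsplit(x, ";\\s*")[[1]]
  if (length(parts) != 7L ||
      !all(substr(parts, 1, 3) == LINEAGE_PREFIXES) ||
      any(nchar(parts) <= 3L)) {
    return(NULL)
  }
  stats::setNames(substring(parts, 4L), RANKS)
}

atomic_write <- function(lines, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' The bundled six-pair 16S sub-region primer panel
#'
#' The panel of commonly used primer pairs targeting V1-V2, V1-V3, V3-V4,
#' V4-V5, V5-V7 and V6-V8, with their nominal amplicon sizes (metadata
#' only; sizes depend on the template and on whether primers are counted).
#'
#' @return A tibble: `region`, `forward`, `reverse`, `size`.
#' @examples
#' default_primer_panel()
#' @export
default_primer_panel <- function() {
  read_primer_panel(system.file("extdata", "primer_panel.tsv",
                                package = "ampliregion", mustWork = TRUE))
}

#' Read a primer panel TSV
#'
#' Expects columns `region`, `forward`, `reverse` and optionally `size`;
#' primer sequences are validated against the IUPAC alphabet and en-dashes
#' in region names are normalized to ASCII hyphens.
#'
#' @param path Path to a tab-separated panel file.
#' @return A tibble.
#' @export
read_primer_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region", "forward", "reverse")
  if (!all(need %in% names(panel))) {
    stop("panel file must have columns region, forward, reverse",
         call. = FALSE)
  }
  panel$region <- gsub("–", "-", panel$region)
  invisible(lapply(panel$forward, check_iupac))
  invisible(lapply(panel$reverse, check_iupac))
  tibble::as_tibble(panel)
}

#' Write reference sequences to FASTA
#'
#' @param db Tibble with `record_id` and `sequence`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(db, path) {
  x <- Biostrings::DNAStringSet(db$sequence)
  names(x) <- db$record_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from FASTA into a tibble
#'
#' @param path FASTA path.
#' @return A tibble with `record_id` (full header line) and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(record_id = names(x),
                 sequence = unname(as.character(x)))
}

#' Write a two-column taxonomy TSV (record id, lineage string)
#'
#' Lineages use the QIIME-style dialect
#' `d__X; p__Y; c__Z; o__W; f__V; g__U; s__T`.
#'
#' @param db Reference tibble with `record_id` and the 7 rank columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_taxonomy <- function(db, path) {
  lin <- vapply(seq_len(nrow(db)), function(i) lineage_string(db[i, ]),
                character(1))
  atomic_write(paste(db$record_id, lin, sep = "\t"), path)
}

#' Read a taxonomy TSV into a record id to lineage table
#'
#' @param path Two-column TSV: record id, QIIME-style lineage string.
#' @return A tibble with `record_id` and the 7 rank columns. Malformed
#'   lines are reported with their line numbers; duplicate ids are an
#'   error; an empty file gives an empty tibble with a warning.
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  empty_out <- tibble::tibble(record_id = character(0))
  if (length(lines) == 0L || all(!nzchar(lines))) {
    warning("taxonomy file is empty: ", path)
    empty_out[RANKS] <- character(0)
    return(empty_out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  parsed <- lapply(fields, function(f) {
    if (length(f) != 2L) NULL else parse_lineage(f[2])
  })
  bad <- sort(union(bad, which(vapply(parsed, is.null, logical(1)))))
  if (length(bad) > 0L) {
    stop("malformed taxonomy line(s) at: ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate record id(s) in taxonomy: ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(do.call(rbind, parsed))
  dplyr::bind_cols(tibble::tibble(record_id = ids), out)
}

#' Write a tibble as TSV with an optional header comment
#'
#' @param x A data frame.
#' @param path Output path.
#' @param comment Optional header comment line(s), written prefixed
#'   with `#`.
#' @return The path, invisibly.
#' @export
write_tsv_report <- function(x, path, comment = NULL) {
  header <- paste(names(x), collapse = "\t")
  body <- do.call(paste, c(lapply(x, as.character), sep = "\t"))
  lines <- c(if (!is.null(comment)) paste0("# ", comment), header, body)
  atomic_write(lines, path)
}
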