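# Independent brute-force oracles and shared fixtures. The oracle code
# deliberately re-derives IUPAC semantics from its own table and scans by
# plain character comparison, so it shares no code path with the package.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_expand <- function(primer) {
  sets <- ORACLE_IUPAC[strsplit(primer, "")[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# expand-and-scan: best Hamming distance over all concrete expansions,
# at every window
oracle_find <- function(sequence, primer, orientation, max_mismatch) {
  pats <- oracle_expand(primer)
  if (orientation == "reverse") {
    pats <- vapply(pats, oracle_revcomp, character(1))
  }
  sch <- strsplit(sequence, "")[[1]]
  L <- nchar(pats[1])
  n <- length(sch)
  if (L > n) return(data.frame(start = integer(0), mismatch = integer(0)))
  best <- rep(Inf, n - L + 1L)
  for (p in pats) {
    pch <- strsplit(p, "")[[1]]
    mm <- integer(n - L + 1L)
    for (j in seq_len(L)) {
      mm <- mm + (sch[j:(j + n - L)] != pch[j])
    }
    best <- pmin(best, mm)
  }
  keep <- which(best <= max_mismatch)
  data.frame(start = keep - 1L, mismatch = as.integer(best[keep]))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# fixtures are built once per test run
.fixtures <- new.env()
cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# 30-species database with the full bundled panel planted, no dropout
fx_planted30 <- function() {
  cached_fixture("planted30", {
    db <- generate_reference_db(n_species = 30, seed = 11)
    plant_primer_sites(db, default_primer_panel(), seed = 12)
  })
}

# mean pairwise sequence identity between two equal-length strings
pair_identity <- function(a, b) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  mean(ac == bc)
}

# random tree with strictly positive branch lengths and its additive
# distance matrix (oracle for neighbor joining)
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.2, 2)
  dm <- cophenetic(tr)
  ord <- sort(rownames(dm))
  list(tree = tr, dm = dm[ord, ord])
}
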