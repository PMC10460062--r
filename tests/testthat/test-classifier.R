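# k-mer naive-Bayes training, bootstrap-confidence classification and
# reclassification scoring.

# hand-built two-species model over k = 4: species sA has counts {3, 1} on
# k-mers AAAA / AAAC, species sB has {1, 3}; Laplace smoothing 1, vocabulary
# 4^4 = 256
toy_model <- function() {
  V <- 256
  counts <- matrix(0, 2, V)
  idx_aaaa <- 1          # AAAA is index 0 in base-4, column 1
  idx_aaac <- 2          # AAAC is index 1
  counts[1, c(idx_aaaa, idx_aaac)] <- c(3, 1)
  counts[2, c(idx_aaaa, idx_aaac)] <- c(1, 3)
  lineage <- tibble::tibble(
    domain = "Bacteria", phylum = "P", class = "C", order = "O",
    family = "F", genus = "G", species = c("sA", "sB")
  )
  structure(
    list(k = 4L, smoothing = 1, species = c("sA", "sB"),
         lineage = lineage,
         log_prob = log(counts + 1) - log(rowSums(counts) + V),
         n_training = 2, fingerprint = 0),
    class = "nb_classifier"
  )
}

test_that("k-mer extraction matches a by-hand enumeration", {
  # ACGTAC: ACGT, CGTA, GTAC; base-4 digits A=0 C=1 G=2 T=3
  idx <- ampliregion:::kmer_indices("ACGTAC", 4)
  hand <- c(
    0 * 64 + 1 * 16 + 2 * 4 + 3,
    1 * 64 + 2 * 16 + 3 * 4 + 0,
    2 * 64 + 3 * 16 + 0 * 4 + 1
  )
  expect_equal(idx, hand)
  expect_null(ampliregion:::kmer_indices("ACG", 4))
})

test_that("posterior scores equal the hand-computed smoothed multinomial", {
  model <- toy_model()
  # query = one AAAA k-mer: score_s = log((count_s + 1) / (4 + 256))
  s <- ampliregion:::nb_scores(model, uidx = 0, ucnt = 1)
  expect_equal(s, log(c(3 + 1, 1 + 1) / (4 + 256)), tolerance = 1e-12)
  # query AAAA x2 + AAAC x1
  s2 <- ampliregion:::nb_scores(model, uidx = c(0, 1), ucnt = c(2, 1))
  expect_equal(
    s2,
    c(2 * log(4 / 260) + log(2 / 260), 2 * log(2 / 260) + log(4 / 260)),
    tolerance = 1e-12
  )
})

test_that("species with disjoint k-mer sets classify with full confidence", {
  db <- tibble::tibble(
    sequence = c(strrep("ACGG", 20), strrep("TTAC", 20)),
    domain = "Bacteria", phylum = c("P1", "P2"), class = c("C1", "C2"),
    order = c("O1", "O2"), family = c("F1", "F2"), genus = c("G1", "G2"),
    species = c("S1", "S2")
  )
  model <- train_nb(db, k = 4)
  res <- classify_sequences(
    tibble::tibble(query_id = c("q1", "q2"), sequence = db$sequence),
    model, n_bootstrap = 50, seed = 1
  )
  expect_identical(res$species, c("S1", "S2"))
  expect_true(all(res$conf_species == 1))
  expect_identical(res$assigned_rank, c("species", "species"))
})

test_that("a single-species database assigns everything to that species", {
  db <- generate_reference_db(n_species = 2, seed = 3,
                              taxonomy_shape = rep(c(1L, 2L), c(6, 1)))
  db1 <- db[1, ]
  model <- train_nb(db1, k = 7)
  res <- classify_sequences(
    tibble::tibble(query_id = "q", sequence = db$sequence[2]),
    model, n_bootstrap = 20, seed = 2
  )
  expect_identical(res$species, db1$species)
  expect_true(all(res[paste0("conf_", ampliregion:::RANKS)] == 1))
})

test_that("n_bootstrap = 0 yields confidence 1 at all ranks (degenerate
           mode)", {
  fx <- fx_planted30()
  model <- train_nb(fx$db, k = 7)
  res <- classify_sequences(
    tibble::tibble(query_id = "q", sequence = fx$db$sequence[5]),
    model, n_bootstrap = 0
  )
  expect_true(all(res[paste0("conf_", ampliregion:::RANKS)] == 1))
  expect_identical(res$species, fx$db$species[5])
})

test_that("per-rank confidences never increase from domain to species", {
  fx <- fx_planted30()
  model <- train_nb(fx$db, k = 7)
  res <- classify_sequences(
    tibble::tibble(query_id = fx$db$record_id[1:10],
                   sequence = fx$db$sequence[1:10]),
    model, n_bootstrap = 30, seed = 4
  )
  confs <- as.matrix(res[paste0("conf_", ampliregion:::RANKS)])
  expect_true(all(diff(t(confs)) <= 1e-12))
})

test_that("queries shorter than k are unclassified with a reason code", {
  fx <- fx_planted30()
  model <- train_nb(fx$db, k = 7)
  res <- classify_sequences(
    tibble::tibble(query_id = "tiny", sequence = "ACGT"), model
  )
  expect_identical(res$assigned_rank, "unclassified")
  expect_identical(res$reason, "shorter_than_k")
})

test_that("full-length self-classification is clean and identity sums hold", {
  fx <- fx_planted30()
  model <- train_nb(fx$db, k = 7)
  queries <- tibble::tibble(
    record_id = fx$db$record_id, region = "full-length",
    sequence = fx$db$sequence
  )
  rep1 <- score_reclassification(queries, fx$db, model, n_bootstrap = 25,
                                 seed = 5)
  expect_true(all(rep1$n_correct + rep1$n_mismatch + rep1$n_unclassified ==
                    rep1$n))
  genus_up <- rep1[rep1$rank %in% c("domain", "phylum", "class", "order",
                                    "family", "genus"), ]
  expect_true(all(genus_up$n_mismatch == 0))
  # n_correct cannot grow with rank depth
  by_depth <- rep1$n_correct[match(ampliregion:::RANKS, rep1$rank)]
  expect_true(all(diff(by_depth) <= 0))
  # determinism
  rep2 <- score_reclassification(queries, fx$db, model, n_bootstrap = 25,
                                 seed = 5)
  expect_identical(
    tibble::as_tibble(rep1)[names(rep1)],
    tibble::as_tibble(rep2)[names(rep2)]
  )
})

test_that("amplicons from a signal-free region truncate at genus while a
           signal-bearing region resolves species", {
  # two congeneric species made identical everywhere except V1
  layout <- region_layout()
  db <- generate_reference_db(n_species = 6, seed = 71, layout = layout)
  v1 <- layout[layout$region == "V1", ]
  a <- db$sequence[db$species == "S001"]
  b <- db$sequence[db$species == "S002"]
  b_new <- a
  substr(b_new, v1$start + 1, v1$end) <- substr(b, v1$start + 1, v1$end)
  db$sequence[db$species == "S002"] <- b_new
  expect_identical(db$genus[1], db$genus[2])

  planted <- plant_primer_sites(db, default_primer_panel(), seed = 72)
  res <- run_insilico_pcr(planted$db, default_primer_panel())
  model <- train_nb(planted$db, k = 7)
  amp <- res$amplicons[res$amplicons$record_id %in% db$record_id[1:2] &
                         res$amplicons$region %in% c("V1-V2", "V3-V4"), ]
  rep <- score_reclassification(amp, planted$db, model, threshold = 0.7,
                                n_bootstrap = 100, seed = 73)
  sp <- rep[rep$rank == "species", ]
  expect_identical(sp$n_correct[sp$region == "V1-V2"], 2L)
  expect_identical(sp$n_unclassified[sp$region == "V3-V4"], 2L)
  gn <- rep[rep$rank == "genus", ]
  expect_true(all(gn$n_correct == gn$n))
})

test_that("orphan amplicons are rejected by name", {
  fx <- fx_planted30()
  model <- train_nb(fx$db, k = 7)
  amp <- tibble::tibble(record_id = "GHOST", region = "V1-V2",
                        sequence = fx$db$sequence[1])
  expect_error(score_reclassification(amp, fx$db, model), "GHOST")
  empty <- score_reclassification(amp[0, ], fx$db, model)
  expect_identical(nrow(empty), 0L)
})
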