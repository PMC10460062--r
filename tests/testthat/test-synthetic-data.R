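# Reference-database generator, site planting with dropout, community
# profiles.

test_that("generator returns the requested records, deterministically", {
  db1 <- generate_reference_db(n_species = 10, seed = 5)
  db2 <- generate_reference_db(n_species = 10, seed = 5)
  db3 <- generate_reference_db(n_species = 10, seed = 6)
  expect_identical(nrow(db1), 10L)
  expect_identical(anyDuplicated(db1$record_id), 0L)
  expect_identical(length(unique(nchar(db1$sequence))), 1L)
  expect_identical(db1, db2)
  expect_false(identical(db1$sequence, db3$sequence))
  # byte-identical FASTA output for a fixed seed
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(db1, f1)
  write_fasta(db2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("fully conserved blocks are identical across all records", {
  layout <- region_layout(conserved_conservation = 1)
  db <- generate_reference_db(n_species = 8, layout = layout, seed = 2)
  for (b in which(grepl("^C", layout$region))) {
    blocks <- substr(db$sequence, layout$start[b] + 1, layout$end[b])
    expect_identical(length(unique(blocks)), 1L)
  }
})

test_that("similarity is hierarchical: genus > phylum > across phyla", {
  db <- generate_reference_db(n_species = 30, seed = 21)
  pairs <- t(combn(nrow(db), 2))
  ident <- apply(pairs, 1, function(ij) {
    pair_identity(db$sequence[ij[1]], db$sequence[ij[2]])
  })
  same_genus <- db$genus[pairs[, 1]] == db$genus[pairs[, 2]]
  same_phylum <- db$phylum[pairs[, 1]] == db$phylum[pairs[, 2]]
  expect_gt(mean(ident[same_genus]),
            mean(ident[same_phylum & !same_genus]))
  expect_gt(mean(ident[same_phylum & !same_genus]),
            mean(ident[!same_phylum]))
})

test_that("an inconsistent taxonomy shape is a configuration error", {
  expect_error(
    generate_reference_db(10, taxonomy_shape = c(1, 3, 2, 4, 5, 6, 10)),
    "non-decreasing"
  )
  expect_error(
    generate_reference_db(10, taxonomy_shape = c(1, 2, 2, 4, 5, 6, 9)),
    "n_species"
  )
})

test_that("planting without dropout leaves no ABSENT ground truth and the
           matcher finds every site at its recorded coordinates", {
  fx <- fx_planted30()
  gt <- fx$ground_truth
  expect_identical(nrow(gt), 30L * 6L * 2L)
  expect_true(all(gt$status == "PRESENT"))
  panel <- default_primer_panel()
  some <- gt[sample(nrow(gt), 40), ]
  for (i in seq_len(nrow(some))) {
    g <- some[i, ]
    s <- fx$db$sequence[fx$db$record_id == g$record_id]
    primer <- if (g$site == "forward") {
      panel$forward[panel$region == g$primer]
    } else {
      panel$reverse[panel$region == g$primer]
    }
    hits <- find_primer_sites(s, primer, g$site, max_mismatch = 0)
    expect_true(any(hits$start == g$start & hits$end == g$end))
  }
})

test_that("delete-site dropout selects exactly floor(fraction * n) records", {
  db <- generate_reference_db(n_species = 80, seed = 31,
                              taxonomy_shape = c(1, 2, 2, 4, 8, 20, 80))
  n_p1 <- sum(db$phylum == "P001")
  expect_identical(n_p1, 40L)
  drop <- dropout_spec("V1-V2", "forward", "phylum", "P001", 0.5, "delete")
  planted <- plant_primer_sites(db, default_primer_panel(), dropout = drop,
                                seed = 32)
  gt <- planted$ground_truth
  absent <- gt[gt$status == "ABSENT", ]
  expect_identical(nrow(absent), 20L)
  expect_true(all(absent$primer == "V1-V2" & absent$site == "forward"))
  p1_ids <- db$record_id[db$phylum == "P001"]
  expect_true(all(absent$record_id %in% p1_ids))
  # the amplified fraction seen by the matcher matches the floor rule
  res <- run_insilico_pcr(planted$db, default_primer_panel())
  v12 <- res$statuses[res$statuses$region == "V1-V2", ]
  expect_identical(sum(v12$status == "AMPLIFIED"), 60L)
  expect_identical(sum(v12$status == "NO_FORWARD"), 20L)
  other <- res$statuses[res$statuses$region != "V1-V2", ]
  expect_true(all(other$status == "AMPLIFIED"))
})

test_that("mutate-k dropout amplifies at max_mismatch >= k only", {
  db <- generate_reference_db(n_species = 10, seed = 41)
  drop <- dropout_spec("V1-V2", "forward", "domain", "Bacteria", 1,
                       "mutate", k = 1)
  planted <- plant_primer_sites(db, default_primer_panel(), dropout = drop,
                                seed = 42)
  strict <- run_insilico_pcr(planted$db, default_primer_panel(),
                             max_mismatch = 0)
  v12 <- strict$statuses[strict$statuses$region == "V1-V2", ]
  expect_true(all(v12$status == "NO_FORWARD"))
  lax <- run_insilico_pcr(planted$db, default_primer_panel(),
                          max_mismatch = 1)
  v12_lax <- lax$statuses[lax$statuses$region == "V1-V2", ]
  expect_true(all(v12_lax$status == "AMPLIFIED"))
})

test_that("community profiles sum to one and honor the dominant share", {
  db <- generate_reference_db(n_species = 12, seed = 51)
  g <- db$genus[1]
  prof <- generate_community(db, n_samples = 3,
                             dominant = list(genus = g, share = 0.5),
                             seed = 52)
  sums <- tapply(prof$abundance, prof$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  g_share <- tapply(
    prof$abundance[prof$taxon %in% db$species[db$genus == g]],
    prof$sample_id[prof$taxon %in% db$species[db$genus == g]], sum
  )
  expect_true(all(abs(g_share - 0.5) < 1e-9))
  # determinism
  expect_identical(prof, generate_community(
    db, n_samples = 3, dominant = list(genus = g, share = 0.5), seed = 52
  ))
})

test_that("sigma = 0 gives equal non-dominant abundances", {
  db <- generate_reference_db(n_species = 9, seed = 61)
  g <- db$genus[1]
  prof <- generate_community(db, sigma = 0,
                             dominant = list(genus = g, share = 0.4),
                             seed = 62)
  rest <- prof$abundance[!prof$taxon %in% db$species[db$genus == g]]
  expect_true(diff(range(rest)) < 1e-12)
  expect_error(generate_community(db[0, ]), "empty")
})
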