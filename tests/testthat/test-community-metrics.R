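# Coverage tables, Chao1/Shannon, rank aggregation, detection overlap and
# the exclusion correlation.

test_that("Chao1 follows the bias-corrected closed form", {
  expect_identical(chao1(c(5, 5, 5)), 3)              # F1 = 0 -> S_obs
  expect_equal(chao1(c(1, 1, 2, 3, 4)), 5 + 2 * 1 / 4, tolerance = 1e-12)
  expect_identical(chao1(c(1)), 1)                    # 1 + 1*0/2
  expect_warning(expect_identical(chao1(c(0, 0)), 0), "zero")
  # Chao1 >= observed richness, equality when no singletons
  set.seed(13)
  for (i in 1:20) {
    counts <- rpois(30, 2)
    counts <- counts[counts > 0]
    if (length(counts) == 0) next
    expect_gte(chao1(counts), length(counts))
    if (sum(counts == 1) == 0) {
      expect_identical(chao1(counts), as.numeric(length(counts)))
    }
  }
})

test_that("Chao1 agrees with the vegan estimator", {
  skip_if_not_installed("vegan")
  set.seed(19)
  for (i in 1:10) {
    counts <- rpois(40, 1.5)
    if (sum(counts) == 0) next
    ref <- unname(vegan::estimateR(counts)["S.chao1"])
    expect_equal(chao1(counts), ref, tolerance = 1e-9)
  }
})

test_that("Shannon entropy matches hand values and the vegan oracle", {
  expect_equal(shannon(c(1, 1, 1, 1), base = 2), 2, tolerance = 1e-12)
  expect_identical(shannon(c(7)), 0)
  expect_equal(shannon(c(3, 1), base = 2),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)),
               tolerance = 1e-12)
  expect_error(shannon(c(0, 0)), "zero")
  skip_if_not_installed("vegan")
  set.seed(23)
  for (i in 1:10) {
    counts <- rpois(25, 3) + 1
    expect_equal(shannon(counts, base = 2),
                 unname(vegan::diversity(counts, base = 2)),
                 tolerance = 1e-9)
    expect_equal(shannon(counts, base = exp(1)),
                 unname(vegan::diversity(counts)), tolerance = 1e-9)
  }
})

test_that("Shannon is maximal at uniform composition", {
  set.seed(29)
  h_max <- shannon(rep(1, 8), base = 2)
  for (i in 1:15) {
    expect_lte(shannon(runif(8, 0.1, 5), base = 2), h_max + 1e-12)
  }
})

test_that("coverage tables reflect planted dropout exactly", {
  db <- generate_reference_db(n_species = 40, seed = 101,
                              taxonomy_shape = c(1, 2, 2, 4, 8, 16, 40))
  drop <- dropout_spec("V1-V2", "forward", "phylum", "P001", 0.5, "delete")
  planted <- plant_primer_sites(db, default_primer_panel(), dropout = drop,
                                seed = 102)
  res <- run_insilico_pcr(planted$db, default_primer_panel())
  cov <- coverage_by_rank(res$statuses, planted$db, rank = "phylum")
  v12 <- cov[cov$region == "V1-V2", ]
  expect_equal(v12$fraction[v12$taxon == "P001"], 0.5, tolerance = 1e-12)
  expect_equal(v12$fraction[v12$taxon == "P002"], 1)
  other <- cov[cov$region != "V1-V2", ]
  expect_true(all(other$fraction == 1))
  # top_n larger than the number of taxa adds no "other" row
  expect_false("other" %in%
                 coverage_by_rank(res$statuses, planted$db, "phylum",
                                  top_n = 50)$taxon)
  # pooling kicks in when top_n is small
  covg <- coverage_by_rank(res$statuses, planted$db, "genus", top_n = 3)
  expect_true("other" %in% covg$taxon)
  expect_error(coverage_by_rank(res$statuses, planted$db, "clade"),
               "unknown rank")
})

test_that("rank aggregation preserves mass and pools unassigned", {
  db <- generate_reference_db(n_species = 12, seed = 111)
  prof <- generate_community(db, n_samples = 2, seed = 112)
  gen <- relative_abundance(prof, db, rank = "genus")
  sums <- tapply(gen$abundance, gen$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # summing the species profile by genus equals the genus profile
  hand <- prof |>
    dplyr::left_join(dplyr::distinct(db[, c("species", "genus")]),
                     by = c(taxon = "species")) |>
    dplyr::group_by(sample_id, genus) |>
    dplyr::summarise(abundance = sum(abundance), .groups = "drop")
  merged <- dplyr::left_join(gen, hand,
                             by = c("sample_id", taxon = "genus"))
  expect_true(all(abs(merged$abundance.x - merged$abundance.y) < 1e-9))
  # single-taxon profile
  single <- relative_abundance(
    tibble::tibble(sample_id = "s", taxon = db$species[1], abundance = 1),
    db, rank = "phylum"
  )
  expect_identical(single$abundance, 1)
  # a species missing from the lineage map pools into "unassigned"
  stray <- relative_abundance(
    tibble::tibble(sample_id = "s", taxon = c(db$species[1], "NOVEL"),
                   abundance = c(0.6, 0.4)),
    db, rank = "genus"
  )
  expect_equal(stray$abundance[stray$taxon == "unassigned"], 0.4)
})

test_that("a planted dominant genus keeps its share after aggregation", {
  db <- generate_reference_db(n_species = 15, seed = 121)
  g <- db$genus[5]
  prof <- generate_community(db, dominant = list(genus = g, share = 0.5),
                             seed = 122)
  gen <- relative_abundance(prof, db, rank = "genus")
  expect_equal(gen$abundance[gen$taxon == g], 0.5, tolerance = 1e-9)
})

test_that("profile correlation matches the stats oracle and the exclusion
           mechanism is exact", {
  p1 <- tibble::tibble(taxon = c("t1", "t2", "t3", "t4", "t5"),
                       abundance = c(0.4, 0.25, 0.15, 0.12, 0.08))
  p2 <- tibble::tibble(taxon = c("t1", "t2", "t3", "t4", "t5"),
                       abundance = c(0.3, 0.3, 0.2, 0.12, 0.08))
  r <- profile_correlation(p1, p2)
  expect_equal(r$r, stats::cor(p1$abundance, p2$abundance),
               tolerance = 1e-12)
  expect_identical(r$n_taxa, 5L)
  # identical profiles -> r = 1
  expect_equal(profile_correlation(p1, p1)$r, 1, tolerance = 1e-12)
  # profiles differing only in one taxon's share: r < 1 before, r = 1 after
  rest <- c(4, 3, 2, 1) / 10
  q1 <- tibble::tibble(taxon = c("big", paste0("t", 1:4)),
                       abundance = c(0.5, rest * 0.5))
  q2 <- tibble::tibble(taxon = c("big", paste0("t", 1:4)),
                       abundance = c(0.2, rest * 0.8))
  expect_lt(profile_correlation(q1, q2)$r, 1 - 1e-6)
  expect_equal(profile_correlation(q1, q2, exclude = "big")$r, 1,
               tolerance = 1e-9)
  # union alignment imputes zeros for missing taxa
  q3 <- tibble::tibble(taxon = c("t1", "t2", "t3"),
                       abundance = c(0.5, 0.3, 0.2))
  q4 <- tibble::tibble(taxon = c("t2", "t3", "t9"),
                       abundance = c(0.5, 0.3, 0.2))
  x <- c(0.5, 0.3, 0.2, 0)
  y <- c(0, 0.5, 0.3, 0.2)
  expect_equal(profile_correlation(q3, q4)$r, stats::cor(x, y),
               tolerance = 1e-12)
  expect_error(profile_correlation(q1[1:2, ], q2[1:2, ]), "fewer than 3")
  flat <- tibble::tibble(taxon = paste0("t", 1:4), abundance = rep(0.25, 4))
  expect_error(profile_correlation(flat, q2[2:5, ]), "zero variance")
})

test_that("detection comparison does plain set algebra", {
  d <- detection_comparison(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_identical(d$n_exclusive, c(1L, 1L))
  expect_identical(d$n_shared, c(2L, 2L))
  expect_true(all(d$n_detected == d$n_exclusive + d$n_shared))
  same <- detection_comparison(list(A = c("x", "y"), B = c("x", "y")))
  expect_identical(same$n_exclusive, c(0L, 0L))
  one_empty <- detection_comparison(list(A = character(0),
                                         B = c("u", "v", "w")))
  expect_identical(one_empty$n_detected, c(0L, 3L))
  expect_identical(one_empty$n_shared, c(0L, 0L))
  expect_identical(one_empty$n_exclusive, c(0L, 3L))
})
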