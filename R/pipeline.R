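# End-to-end orchestration: simulate -> pcr -> classify -> trees -> metrics,
# with a single explicit-seed config, deterministic outputs and atomic
# report writing.

#' Build a pipeline configuration
#'
#' All seeds are explicit (sub-stage seeds are derived from `seed` by fixed
#' offsets; there is no wall-clock seeding), so a config determines the
#' whole report bundle byte-for-byte. The default scenario plants the
#' bundled six-pair panel into a synthetic database and recreates the
#' study's qualitative conditions: two primer pairs that miss a large slice
#' of one phylum, one pair that misses most of a second phylum, and partial
#' dropout of the dominant genus for one scheme so that the
#' dominant-taxon-exclusion correlation has something to detect.
#'
#' @param seed Master integer seed.
#' @param n_species Synthetic database size (one record per species).
#' @param taxonomy_shape Optional 7-rank group counts
#'   (see [generate_reference_db()]).
#' @param layout A [region_layout()].
#' @param panel Primer panel tibble (default [default_primer_panel()]).
#' @param dropout Dropout table ([dropout_spec()] rows) or `NULL` to use
#'   the default scenario above.
#' @param max_mismatch,mode In silico PCR settings.
#' @param k,threshold,n_bootstrap Classifier settings.
#' @param tree_k k-mer length for tree distances.
#' @param n_samples,mu,sigma,dominant Community simulation settings;
#'   `dominant` defaults to pinning genus `"G001"` at a 0.35 share.
#' @param correlate Length-2 character: the two schemes whose genus-level
#'   profiles are correlated (default `c("V1-V2", "V3-V4")`).
#' @param depth Sequencing depth used to turn relative abundances into
#'   integer counts for Chao1.
#' @param stages Subset of
#'   `c("simulate", "pcr", "classify", "trees", "metrics")`; later stages
#'   require earlier ones.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_species = 60L,
                            taxonomy_shape = NULL,
                            layout = region_layout(),
                            panel = default_primer_panel(),
                            dropout = NULL,
                            max_mismatch = 0L,
                            mode = "included",
                            k = 7L,
                            threshold = 0.7,
                            n_bootstrap = 100L,
                            tree_k = 8L,
                            n_samples = 5L,
                            mu = 0,
                            sigma = 1,
                            dominant = list(genus = "G001", share = 0.35),
                            correlate = c("V1-V2", "V3-V4"),
                            depth = 20000L,
                            stages = c("simulate", "pcr", "classify",
                                       "trees", "metrics")) {
  if (is.null(dropout)) {
    dropout <- dplyr::bind_rows(
      dropout_spec("V1-V3", "forward", "phylum", "P001", 0.6, "delete"),
      dropout_spec("V6-V8", "reverse", "phylum", "P001", 0.5, "delete"),
      dropout_spec("V4-V5", "forward", "phylum", "P002", 0.8, "delete"),
      dropout_spec("V1-V2", "forward", "genus", dominant$genus, 0.7,
                   "delete")
    )
  }
  config <- list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    taxonomy_shape = taxonomy_shape, layout = layout, panel = panel,
    dropout = dropout, max_mismatch = max_mismatch, mode = mode,
    k = k, threshold = threshold, n_bootstrap = n_bootstrap,
    tree_k = tree_k, n_samples = n_samples, mu = mu, sigma = sigma,
    dominant = dominant, correlate = correlate, depth = depth,
    stages = stages
  )
  class(config) <- "pipeline_config"
  config
}

#' Write / read a pipeline configuration as YAML
#'
#' The config round-trips losslessly: reading a written file reproduces a
#' config with the same hash, so a YAML file fully determines a pipeline
#' run.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  for (tb in c("layout", "panel", "dropout")) {
    if (!is.null(x[[tb]])) x[[tb]] <- as.list(as.data.frame(x[[tb]]))
  }
  atomic_write(yaml::as.yaml(x), path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (tb in c("layout", "panel", "dropout")) {
    if (!is.null(x[[tb]])) x[[tb]] <- tibble::as_tibble(x[[tb]])
  }
  config <- pipeline_config()
  for (nm in names(x)) {
    if (!is.null(x[[nm]])) config[[nm]] <- x[[nm]]
  }
  config$seed <- as.integer(config$seed)
  config$n_species <- as.integer(config$n_species)
  config
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(
    unclass(config), auto_unbox = TRUE, digits = NA, null = "null"
  )), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full in silico primer-evaluation pipeline
#'
#' Simulates (or accepts) a reference database, runs in silico PCR for the
#' panel, scores amplicon re-classification, builds per-region trees and
#' their Robinson-Foulds concordance with the full-length tree, and
#' computes community metrics (coverage, alpha diversity per scheme,
#' detection overlap, exclusion correlation). Deterministic for a fixed
#' config.
#'
#' @param config A [pipeline_config()].
#' @param db Optional externally supplied reference tibble (e.g. a real
#'   curated 16S set read with [read_fasta()] + [read_taxonomy()]); when
#'   given, the simulate stage only generates the community profiles and
#'   the sequences are used as-is (no site planting).
#' @return An `ampliregion_bundle` list of result tables plus a `summary`
#'   list; see [write_report()].
#' @export
run_pipeline <- function(config = pipeline_config(), db = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  bundle <- list(config = config, config_hash = config_hash(config))

  if ("simulate" %in% stages) {
    if (is.null(db)) {
      raw <- generate_reference_db(
        config$n_species, taxonomy_shape = config$taxonomy_shape,
        layout = config$layout, seed = config$seed
      )
      planted <- plant_primer_sites(raw, config$panel,
                                    layout = config$layout,
                                    dropout = config$dropout,
                                    seed = config$seed + 1L)
      db <- planted$db
      bundle$ground_truth <- planted$ground_truth
    }
    bundle$db <- db
    bundle$community <- generate_community(
      db, n_samples = config$n_samples, mu = config$mu,
      sigma = config$sigma, dominant = config$dominant,
      seed = config$seed + 2L
    )
  }
  if (is.null(bundle$db)) stop("pipeline needs the simulate stage or a db",
                               call. = FALSE)

  if ("pcr" %in% stages) {
    pcr <- run_insilico_pcr(bundle$db, config$panel,
                            max_mismatch = config$max_mismatch,
                            mode = config$mode)
    bundle$amplicons <- pcr$amplicons
    bundle$statuses <- pcr$statuses
  }

  if ("classify" %in% stages) {
    if (is.null(bundle$amplicons)) stop("classify stage requires pcr",
                                        call. = FALSE)
    model <- train_nb(bundle$db, k = config$k)
    queries <- dplyr::bind_rows(
      tibble::tibble(record_id = bundle$db$record_id,
                     region = "full-length",
                     sequence = bundle$db$sequence),
      bundle$amplicons[, c("record_id", "region", "sequence")]
    )
    bundle$reclassification <- score_reclassification(
      queries, bundle$db, model, threshold = config$threshold,
      n_bootstrap = config$n_bootstrap, seed = config$seed + 3L
    )
    bundle$misclassification <-
      misclassification_by_genus(bundle$reclassification)
    bundle$model <- model
  }

  if ("trees" %in% stages) {
    bundle$concordance <- region_concordance(
      bundle$db, config$panel, k = config$tree_k,
      max_mismatch = config$max_mismatch, mode = config$mode
    )
  }

  if ("metrics" %in% stages) {
    if (is.null(bundle$statuses)) stop("metrics stage requires pcr",
                                       call. = FALSE)
    bundle$coverage_phylum <- coverage_by_rank(bundle$statuses, bundle$db,
                                               rank = "phylum")
    bundle$coverage_genus <- coverage_by_rank(bundle$statuses, bundle$db,
                                              rank = "genus", top_n = 15)
    if (!is.null(bundle$community)) {
      schemes <- unique(config$panel$region)
      detected <- purrr::map(stats::setNames(schemes, schemes), function(rg) {
        ok <- bundle$statuses$record_id[
          bundle$statuses$region == rg &
            bundle$statuses$status == "AMPLIFIED"]
        bundle$db$species[bundle$db$record_id %in% ok]
      })
      bundle$detection <- detection_comparison(detected)
      # per-scheme detected community: drop missed species, renormalize
      scheme_profiles <- lapply(schemes, function(rg) {
        prof <- bundle$community[bundle$community$taxon %in%
                                   detected[[rg]], ]
        prof |>
          dplyr::group_by(.data$sample_id) |>
          dplyr::mutate(abundance = .data$abundance /
                          sum(.data$abundance)) |>
          dplyr::ungroup() |>
          dplyr::mutate(scheme = rg)
      })
      names(scheme_profiles) <- schemes
      bundle$alpha_diversity <- dplyr::bind_rows(lapply(
        scheme_profiles, function(prof) {
          prof |>
            dplyr::mutate(abundance = round(.data$abundance *
                                              config$depth)) |>
            alpha_diversity() |>
            dplyr::mutate(scheme = prof$scheme[1])
        }
      ))
      genus_profiles <- lapply(scheme_profiles, function(prof) {
        relative_abundance(prof, bundle$db, rank = "genus") |>
          dplyr::group_by(.data$taxon) |>
          dplyr::summarise(abundance = mean(.data$abundance),
                           .groups = "drop") |>
          dplyr::mutate(abundance = .data$abundance /
                          sum(.data$abundance))
      })
      bundle$genus_profiles <- dplyr::bind_rows(
        lapply(schemes, function(rg) {
          dplyr::mutate(genus_profiles[[rg]], scheme = rg)
        })
      )
      s1 <- config$correlate[1]
      s2 <- config$correlate[2]
      bundle$correlation <- tibble::tibble(
        scheme_1 = s1,
        scheme_2 = s2,
        r_all = profile_correlation(genus_profiles[[s1]],
                                    genus_profiles[[s2]])$r,
        r_excluded = profile_correlation(
          genus_profiles[[s1]], genus_profiles[[s2]],
          exclude = config$dominant$genus
        )$r,
        excluded_taxon = config$dominant$genus
      )
    }
  }

  bundle$summary <- bundle_summary(bundle)
  class(bundle) <- "ampliregion_bundle"
  bundle
}

# machine-readable roll-up of the bundle's headline numbers
bundle_summary <- function(bundle) {
  s <- list(config_hash = bundle$config_hash)
  if (!is.null(bundle$statuses)) {
    cov <- bundle$statuses |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(fraction = mean(.data$status == "AMPLIFIED"))
    s$coverage_fraction <- as.list(stats::setNames(cov$fraction,
                                                   cov$region))
  }
  if (!is.null(bundle$reclassification)) {
    sp <- bundle$reclassification[
      bundle$reclassification$rank == "species", ]
    s$species_pct_correct <- as.list(stats::setNames(sp$pct_correct,
                                                     sp$region))
  }
  if (!is.null(bundle$concordance)) {
    s$rf_normalized <- as.list(stats::setNames(
      bundle$concordance$rf_normalized, bundle$concordance$region))
  }
  if (!is.null(bundle$alpha_diversity)) {
    ad <- bundle$alpha_diversity |>
      dplyr::group_by(.data$scheme) |>
      dplyr::summarise(chao1 = mean(.data$chao1),
                       shannon = mean(.data$shannon))
    s$mean_chao1 <- as.list(stats::setNames(ad$chao1, ad$scheme))
    s$mean_shannon <- as.list(stats::setNames(ad$shannon, ad$scheme))
  }
  if (!is.null(bundle$detection)) {
    s$n_species_detected <- as.list(stats::setNames(
      bundle$detection$n_detected, bundle$detection$scheme))
    s$n_species_exclusive <- as.list(stats::setNames(
      bundle$detection$n_exclusive, bundle$detection$scheme))
  }
  if (!is.null(bundle$correlation)) {
    s$correlation_all_taxa <- bundle$correlation$r_all
    s$correlation_dominant_excluded <- bundle$correlation$r_excluded
  }
  s
}

#' Write a pipeline report bundle to a directory
#'
#' Emits the result tables as TSV (each with the config hash in a header
#' comment), the reference FASTA + taxonomy, the amplicon FASTA, a
#' machine-readable `summary.json` and a human-readable `summary.txt`.
#' All writes are atomic (temp file then rename).
#'
#' @param bundle An [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ampliregion_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- paste("config:", bundle$config_hash)
  tables <- c("ground_truth", "statuses", "reclassification",
              "misclassification", "concordance", "coverage_phylum",
              "coverage_genus", "alpha_diversity", "genus_profiles",
              "detection", "correlation", "community")
  for (tb in tables) {
    if (!is.null(bundle[[tb]])) {
      write_tsv_report(bundle[[tb]], file.path(dir, paste0(tb, ".tsv")),
                       comment = hash)
    }
  }
  if (!is.null(bundle$db)) {
    write_fasta(bundle$db, file.path(dir, "references.fasta"))
    write_taxonomy(bundle$db, file.path(dir, "taxonomy.tsv"))
  }
  if (!is.null(bundle$amplicons) && nrow(bundle$amplicons) > 0L) {
    amp <- bundle$amplicons
    write_fasta(
      tibble::tibble(
        record_id = sprintf("%s|%s|%d-%d|%s", amp$record_id, amp$region,
                            amp$start, amp$end, amp$mode),
        sequence = amp$sequence
      ),
      file.path(dir, "amplicons.fasta")
    )
  }
  atomic_write(
    as.character(jsonlite::toJSON(bundle$summary, auto_unbox = TRUE,
                                  digits = NA, null = "null")),
    file.path(dir, "summary.json")
  )
  txt <- c(
    "ampliregion pipeline summary",
    paste("config hash:", bundle$config_hash),
    "",
    utils::capture.output(utils::str(bundle$summary, give.attr = FALSE))
  )
  atomic_write(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.ampliregion_bundle <- function(x, ...) {
  cat("ampliregion pipeline bundle (config", substr(x$config_hash, 1, 8),
      ")\n")
  cat("  tables:", paste(intersect(
    c("ground_truth", "statuses", "amplicons", "reclassification",
      "concordance", "coverage_phylum", "coverage_genus",
      "alpha_diversity", "detection", "correlation"),
    names(x)
  ), collapse = ", "), "\n")
  invisible(x)
}
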