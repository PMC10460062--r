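# ampliregion

In silico evaluation of 16S rRNA sub-region primer pairs.

Amplicon microbiome surveys sequence a short stretch of the bacterial 16S
rRNA gene — nine variable regions V1–V9 interleaved among conserved blocks
— and the choice of primer pair decides which taxa are seen at all, whether
the amplicon can be re-identified to species, how faithful a per-region
phylogeny is, and how distorted community profiles become when an abundant
genus amplifies unevenly. `ampliregion` is for microbiome researchers who
want those four properties measured, per primer pair, before committing a
study to one region.

The package provides, behind one pipeline:

* **In silico PCR** — IUPAC-degenerate primer matching (a position matches
  iff the template base is in the code's set; mismatch = number of
  incompatible positions) and amplicon extraction per record × region,
  with per-record amplification statuses.
* **Taxonomy re-classification** — a k-mer multinomial naive-Bayes
  classifier, log P(w|s) = log((c\_sw + α)/(Σc + α·4^k)), with RDP-style
  bootstrap confidence (resample ⌈m/8⌉ of the query's m k-mers, 100
  replicates) and lineage truncation at the deepest rank reaching the
  confidence threshold; per-rank correct/mismatch/unclassified scoring of
  amplicons against their source records.
* **Tree concordance** — k-mer Jaccard (or p-distance on aligned input)
  distance matrices, Saitou–Nei neighbor joining (exact on additive
  matrices), and Robinson–Foulds bipartition distance of each region tree
  to the full-length tree, normalized by 2(n−3).
* **Community metrics** — per-taxon coverage tables, bias-corrected Chao1
  (S\_obs + F₁(F₁−1)/(2(F₂+1))), Shannon entropy, detection overlap
  between schemes, and the dominant-taxon-exclusion Pearson correlation
  between two schemes' profiles.
* **A synthetic 16S-like simulator** — clade-hierarchical sequence
  generation over a 7-rank taxonomy, planted primer sites with exact
  ground truth, per-clade site dropout (floor rule, exactly recoverable),
  and log-normal communities with a pinned dominant genus — so the whole
  pipeline runs and is testable with no external database. A real
  reference set (FASTA + lineage TSV) can be dropped in instead.

The six-pair panel targeting V1–V2, V1–V3, V3–V4, V4–V5, V5–V7 and V6–V8
is bundled (`default_primer_panel()`).

## Worked example

```r
library(ampliregion)
bundle <- run_pipeline(pipeline_config(seed = 1))
glance(bundle)
#> # A tibble: 1 × 6
#>   n_species mean_coverage mean_species_pct_correct mean_rf_normalized
#> 1        60          0.85                      100             0.0741
#>   correlation_all_taxa correlation_dominant_excluded
#> 1                0.965                         0.996
```

The default scenario (60 synthetic species, the bundled panel, planted
per-clade dropout) reproduces the qualitative phenomena the pipeline is
built to measure. Coverage: the V4–V5 pair misses 80% of phylum `P002`
while V3–V4 amplifies everything —

```r
dplyr::filter(bundle$coverage_phylum, region %in% c("V3-V4", "V4-V5"))
#>   region taxon n_input n_amplified fraction
#> 1 V3-V4  P002       45          45      1
#> 2 V3-V4  P001       15          15      1
#> 3 V4-V5  P002       45           9      0.2
#> 4 V4-V5  P001       15          15      1
```

Tree concordance: regions whose primers amplify everything reproduce the
full-length topology (normalized RF 0), while the dropout-affected V4–V5
tree drifts away (0.222 on the 12 records shared by all regions):

```r
bundle$concordance
#>   region n_taxa    rf rf_normalized
#> 1 V1-V2      12     0         0
#> 2 V3-V4      12     0         0
#> 3 V4-V5      12     4         0.222
#> ...
```

Dominant-taxon exclusion: the V1–V2 scheme drops part of the dominant
genus `G001`, depressing the genus-level correlation between the V1–V2 and
V3–V4 profiles; excluding `G001` and renormalizing restores it:

```r
bundle$correlation
#>   scheme_1 scheme_2 r_all r_excluded excluded_taxon
#> 1 V1-V2    V3-V4    0.965      0.996 G001
```

`write_report(bundle, "report")` writes every table as TSV (each stamped
with the config hash), the reference/amplicon FASTA, and a
machine-readable `summary.json`. `autoplot()` methods exist for coverage
tables, reclassification reports and concordance tables.

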