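---
title: "Evaluating 16S rRNA sub-region primer pairs in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating 16S rRNA sub-region primer pairs in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ampliregion)
library(dplyr)
```

## The problem

Amplicon surveys of bacterial communities sequence a short stretch of the
16S rRNA gene — a ~1.5 kb marker with nine variable regions (V1–V9)
interleaved among highly conserved blocks. Which variable regions a primer
pair brackets determines (i) which taxa amplify at all (primer-template
compatibility differs by clade), (ii) whether the amplicon still carries
enough signal to re-identify its source at the species level, (iii) how
faithfully a tree built from the amplicons reproduces the phylogeny of the
full-length gene, and (iv) how distorted the resulting community profile
is when an abundant genus is differentially amplified. `ampliregion`
implements all four measurements behind one pipeline, together with a
synthetic reference-database generator so every property is testable
without downloading a curated database.

## Pipeline stages and their models

### In silico PCR

A degenerate primer is a string over the IUPAC alphabet; a primer position
*matches* a template base iff the base belongs to the code's set, and a
site's mismatch count is the number of incompatible positions.
`find_primer_sites()` scans the forward strand for the forward primer and
for the reverse complement of the reverse primer; `run_insilico_pcr()`
pairs sites (forward strictly upstream) and extracts one amplicon per
record and region. Defaults, all configurable:

* `max_mismatch = 0` — trimming against reference sequences implies exact
  degenerate matching.
* `mode = "included"` — the amplicon spans both primer sites, which is
  what a sequencer reads; `"excluded"` (insert only) is equally supported
  since published amplicon sizes do not always state the convention.
* `product_size_bounds = c(50, 2000)` bp — suppresses spurious pairings;
  all 16S sub-region products fall well inside.
* Several valid pairings give status `MULTIPLE_PRODUCTS` and the shortest
  product, which is deterministic and conservative.
* `U` is normalized to `T`.

The matcher is bit-encoded (base sets as 4-bit masks) and is verified in
the test suite against a brute-force oracle that expands each degenerate
primer into all concrete strings (the bundled panel's degeneracies are at
most 8) and scans by Hamming distance.

### Taxonomic re-classification

`train_nb()` fits a multinomial naive-Bayes model over k-mer counts per
species with Laplace smoothing:
$\log P(w \mid s) = \log\frac{c_{sw} + \alpha}{\sum_w c_{sw} + \alpha 4^k}$.
A query is assigned the species maximizing the summed log-probability of
its k-mer multiset. Confidence at each rank is bootstrap-based: the query's
$m$ k-mers are resampled with replacement ($\lceil m/8 \rceil$ per
replicate, 100 replicates), and the confidence at a rank is the fraction
of replicate winners agreeing with the point assignment there; the lineage
is truncated at the deepest rank reaching the threshold. Defaults `k = 7`,
`smoothing = 1`, `threshold = 0.7` follow the common settings of this
classifier family.

One numerical choice matters and was genuinely open. Point-assignment ties
are broken by lexicographic species label, which keeps the point estimate
deterministic. Inside bootstrap replicates, however, ties are broken
uniformly at random (under the caller's seed): two species whose training
sequences are identical over every region an amplicon covers are
*genuinely indistinguishable*, and a deterministic tie-break would report
confidence 1.0 for one of them. Random tie-breaking makes the vote split
roughly evenly, the species-level confidence falls below any reasonable
threshold, and the assignment truncates at the genus — which is the
behaviour a user should want from amplicons that carry no species-level
signal. `n_bootstrap = 0` is a documented degenerate mode in which the
point assignment gets confidence 1 at every rank (top-hit classification
without a cutoff, for users who want the paper-style raw assignment).

`score_reclassification()` compares each amplicon's assignment with its
source record's lineage: per rank, *correct* / *mismatch* / *unclassified*
(truncated above that rank) always sum to the number of amplicons.

### Tree concordance

The default distance is the alignment-free k-mer Jaccard distance
(`k = 8`): $d(a,b) = 1 - |K_a \cap K_b| / |K_a \cup K_b|$. Re-implementing
a production multiple aligner is out of scope for this package;
`p_distance()` (proportion of differing sites over gap-free columns) is
provided for users who supply an externally aligned FASTA, and the
concordance conclusions concern *relative* tree similarity, which is
testable under either metric. Trees are built with `neighbor_joining()`
(Saitou–Nei): Q-criterion ties are broken by the smallest index pair,
negative branch lengths are clamped to zero with the deficit moved to the
sibling branch, and the reconstruction is exact on additive matrices (a
tested invariant). `robinson_foulds()` counts bipartitions present in
exactly one tree, ignoring branch lengths — a topological comparison, with
the normalized form dividing by $2(n-3)$. `region_concordance()` drops
records not amplified by every region so all trees share a leaf set, and
reports each region tree's RF distance to the full-length tree built with
the same distance. Any species subset (e.g. a periodontal-pathogen list)
can be passed as a filter.

### Community metrics

* Chao1 uses the bias-corrected form
  $S_{obs} + F_1(F_1-1) / (2(F_2+1))$, which stays finite when there are
  no doubletons; it equals observed richness whenever singletons are
  absent.
* Shannon entropy defaults to log base 2 (bits); natural log is available
  via `base`. The choice of base rescales but never reorders samples.
* `relative_abundance()` sums species-level abundances up the lineage;
  assignments truncated above the target rank pool into `"unassigned"`.
* `profile_correlation()` aligns two profiles on the union of their taxa
  (absent taxa imputed 0), excludes `"unassigned"` (only named taxa are
  compared), and optionally removes one taxon from both profiles and
  renormalizes before computing Pearson's r. This is the
  dominant-taxon-exclusion analysis: when one abundant taxon is the sole
  source of disagreement between two schemes, its exclusion drives r to 1
  exactly — a limit the test suite asserts.

## The synthetic generator: what it emulates

`generate_reference_db()` draws a root sequence and mutates it down a
nested 7-rank taxonomy; each clade inherits its parent's sequence with
per-position substitution probability `rank_rate * (1 - conservation)`.
The default layout is ten conserved blocks of 65 bp around nine variable
regions of 90 bp (≈1.46 kb, the real gene's scale), with conservation
0.95 in conserved blocks and 0.25 in variable regions, and per-rank rates
0.14 (phylum) down to 0.04 (species). These values were chosen once to
give realistic within-genus (~95%) versus cross-phylum (~75–85%) identity
and are not tuned to any test: the package's guarantees are structural
(planted ground truth, closed forms, oracle equivalence), not threshold
chases.

`plant_primer_sites()` writes one concrete realization of each degenerate
primer into the conserved block flanking its region span, right-aligned
for forward sites and left-aligned for reverse sites, stacking multiple
primers sharing a block. Two details are worth knowing:

* Several real 16S primers overlap the same conserved motif — the V4–V5
  forward primer (515F family) contains the full reverse complement of
  the V1–V3 reverse primer (519R family). Planted naively, one primer's
  site would be a second exact site for another primer. The planter
  therefore verifies candidate realizations with the matcher itself and
  (a) redraws realizations when an off-target window lies inside planted
  sites, (b) breaks windows that extend into free template by switching
  one background base to a primer-incompatible one. The post-condition is
  exact: every record carries exactly one zero-mismatch site per planted
  primer, and the returned ground-truth table records its coordinates.
* Dropout (`dropout_spec()`) deletes or mutates a site in
  `floor(fraction * n)` records of a clade after a seeded shuffle — the
  floor rule makes planted coverage fractions exactly recoverable.

`generate_community()` draws species abundances i.i.d. log-normal and can
pin one genus at a fixed share (the oral-cavity situation where one genus
dwarfs the rest). The default pipeline scenario plants differential
coverage — two primer pairs missing a large slice of one phylum, one pair
missing most of another, and the dominant genus partially dropped for one
scheme — so that every downstream measurement has signal to detect.

What the generator does **not** emulate: read-level error profiles,
paired-end merging, chimeras, copy-number variation, platform quality
differences, and the true sequence composition of any curated database.
Green tests therefore demonstrate that the *measurement machinery* is
correct on data whose ground truth is known, not that any specific primer
pair is best on real communities. A real reference set can be supplied via
`read_fasta()` + `read_taxonomy()` and passed to `run_pipeline()` as-is.

## Problem sizes

The test suite exercises the matcher–oracle equivalence on 500 random
1 kb sequences for the whole panel at 0–1 mismatches; coverage and
classifier properties on a 200-species database (5 phyla of 40 species,
100 bootstrap replicates); neighbor-joining exactness on 100 random
additive matrices of 4–8 taxa; concordance direction on ten 20-species
databases with divergence confined to V1–V2; and full-pipeline determinism
at the default 60-species scale. These sizes were chosen to make every
property decidable in seconds to a few minutes on a laptop while keeping
each phylum, genus and region populated enough for the statistics to be
meaningful.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1)
bundle <- run_pipeline(cfg)
glance(bundle)
bundle$coverage_phylum |> filter(region == "V4-V5")
autoplot(bundle$concordance)
write_report(bundle, "report")
```

## Known limitations

* The k-mer Jaccard distance saturates for very divergent sequences and
  ignores alignment; concordance values are comparable *between regions
  under the same distance*, not across distances.
* Bootstrap confidences are Monte-Carlo estimates; with 100 replicates
  their standard error near 0.5 is ≈0.05, so thresholds should not be
  read as sharp boundaries.
* Nominal amplicon sizes shipped with the panel are metadata only; actual
  product sizes depend on the template and the primer-inclusion
  convention.
* The planted-site guarantee is for exact matching; at `max_mismatch >= 1`
  overlapping conserved motifs between real primers can legitimately
  produce secondary near-matches (reported as `MULTIPLE_PRODUCTS`).
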