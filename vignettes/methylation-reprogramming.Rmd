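---
title: "Tile-based analysis of methylation reprogramming in gametes and preimplantation embryos"
author: "methrepro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-based analysis of methylation reprogramming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrepro)
```

## The analysis problem

Between fertilisation and the blastocyst stage, mammalian embryos reset most
of the DNA methylation inherited from the gametes. Sperm arrives almost
uniformly hypermethylated; the oocyte brings a mosaic methylome of
alternating hypermethylated and hypomethylated domains, with methylation
concentrated over the bodies of expressed genes. The paternal genome is
demethylated rapidly after fertilisation, the maternal genome more slowly,
so cleavage embryos carry an oocyte-like pattern at decreasing overall
levels until a species-specific minimum around the blastocyst. Imprinted
loci are the exception: their germline differentially methylated regions
(gDMRs) are methylated on one parental allele only, and an unphased
methylome should hold them near 50% through cleavage — possibly after a
transient dip and recovery.

Whole-genome bisulfite data from these samples are sparse (tens of cells,
post-bisulfite adaptor tagging libraries), so single-CpG estimates are
unreliable. The established remedy, which this package implements as a
reusable, tested pipeline, is to aggregate calls over *non-overlapping
windows of exactly 100 consecutive CpGs* and to run every downstream
analysis — global levels, domain segmentation, gDMR screening,
stage-change detection, methylation–expression correlation — at the tile or
feature level.

## Quantitation model

A sample is a set of per-CpG counts (methylated, unmethylated). For a
feature (tile, CpG island, domain, promoter, gene body):

* a CpG contributes if its coverage is at least `min_count` reads
  (default 1);
* each contributing CpG yields its own percentage
  $100\,m_i/(m_i+u_i)$;
* the feature value is the **unweighted mean of per-position
  percentages** — the semantics of the SeqMonk bisulfite pipeline — so a
  deeply covered CpG does not dominate its neighbours. A pooled-count mode
  (`aggregate = "pooled"`) is available for sensitivity analysis;
* the feature is reported missing unless it reaches an inclusion
  threshold: 5 observed positions for tiles and repeats, 10 for CpG
  islands, domains and intergenic regions, or — for curated imprinted-gene
  features — 10 total methylation calls (`quant_config(unit = "calls")`).
  Missing is a value, never an error.

Thresholds are compared exactly (no epsilon); values are percentages in
double precision. A tile is *informative* when it is quantifiable in all
six stages (sperm, oocyte, 2–4 cell, 8–16 cell, morula, blastocyst). The
filter has a second, literal reading in which a value of exactly 0 also
disqualifies a tile; that reading would discard fully unmethylated CpG
island tiles which plainly belong in the 0–10% histogram bin, so
`informative_filter()` defaults to "has data in all six" and exposes
`"literal_above_zero"` for comparison.

## Domain segmentation

Oocyte HyperDomains and HypoDomains are maximal runs of consecutive
same-chromosome tiles with oocyte methylation ≥ 75% (hyper) or ≤ 25%
(hypo), both inclusive. Published domain callers in this literature rarely
state their exact merge rule, so the rule here is the simplest one
consistent with tile-level analysis, with two declared choices:

* `max_gap_tiles` (default 0) value-missing tiles may sit inside a run
  without breaking it (they are never members); intermediate-methylation
  tiles always break runs;
* no minimum domain length (a single qualifying tile is a domain), so
  median-size statistics are meaningful and configurable upstream.

Genome coverage is reported against the *queried genome* — the summed span
of informative tiles — because uninformative regions cannot be classified
either way. Domain trajectories across stages are re-quantified per domain
(10-position threshold) and compared between stages with a two-sided
Mann–Whitney rank test (`stage_shift_test()`).

## Gametic DMRs and imprint candidates

Two threshold conventions coexist in the field and both are implemented:
*strict* (> 75 and < 25, the DMR-calling convention; the default for
screening) and *inclusive* (≥ 75 / ≤ 25, the state-assignment convention).
Boundary features are rare; the flag `strict` harmonises them.
`classify_gametic()` assigns each feature one of five states —
oocyte-specific DMR, sperm-specific DMR, both-hyper, both-hypo, neither.

An imprint candidate is a gametic DMR that retains intermediate
methylation, 30–70% inclusive, in the blastocyst. The screen's scope is
the blastocyst value only by default: a gDMR may dip below 30% transiently
at the 8–16 cell stage before recovering — exactly the behaviour the
generator's trajectory archetypes emulate — and a filter across all embryo
stages would discard such loci; `scope = "all_embryo_stages"` provides the
stringent alternative. The screen runs at tile level and at CpG-island
level (the island analogue of the candidate lists), candidates are flagged
for ≥ 1 bp CpG-island overlap, and are mapped to the nearest gene by
signed gap distance, assigned when |distance| < 50 kb.

Stage-to-stage de novo methylation is detected by `delta_tiles()`: among
informative tiles with values at both stages, gains change by more than
+10 percentage points (strict, absolute points — all comparisons in this
pipeline are on the percent scale) and losses by more than −10.
Annotation enrichment of any tile set uses per-class 2×2 tables against
the remaining background, chi-square without continuity correction
(configurable), enrichment ratio defined against the *full* background so
a set equal to its background has ratio exactly 1, and
Benjamini–Hochberg-adjusted p values reported alongside raw ones as good
practice.

Candidate trajectories (rows = candidates, columns = embryo stages) are
clustered by centring the matrix, projecting on the first two principal
components and partitioning with k-means (k = 2 by default, 10 restarts,
mandatory seed). A two-component PCA separation admits several
partitioners; k-means is the simplest deterministic one, the result is
reproducible given the seed and invariant to cluster-label permutation.

## Expression coupling

Expression is quantified as log2 fragments per million,
$\log_2(10^6 c / N + 1)$; the +1 FPM pseudocount keeps zero counts at
exactly 0, avoids minus infinity, and is configurable.
Promoters are strand-aware windows of 1500 bp upstream and 500 bp
downstream of the TSS (minus-strand windows are exact mirror images;
an alternative TSS-inclusive convention would shift them by one base and
is deliberately not the default). `meth_expr_correlation()` builds the
stage × stage Pearson matrix over a gene list with pairwise-complete
deletion (cells with < 3 pairs or a constant margin are NA);
`genebody_meth_vs_expr()` bins genes by body methylation and reports a
Spearman trend. The demethylated-promoter test selects promoters
hypermethylated in a gamete (≥ 75%) that drop by **more than 50 percentage
points** by the 2–4 cell stage — read as absolute points, not relative
halving, consistent with every other percent-scale comparison — and asks
whether their genes change expression (> 2-fold on the FPM scale, i.e.
|Δlog2 FPM| > 1) more often than other promoters, by the same chi-square.
The expression stage pair defaults to 2–4 → 8–16 cells, the first
comparison available after the demethylation is assessed, and is
configurable.

## The synthetic-data generator

Every planted-truth test in the package is driven by `sim_config()` /
`simulate_methylome_study()`; nothing is downloaded and no large fixture is
shipped. The generator emulates, per seeded draw:

* a genome of 3 × 8 Mb chromosomes; background CpGs at a mean spacing of
  100 bp with ~10× denser CpG islands (1 kb) at half of the promoters plus
  standalone islands; genes, SINE/LINE repeats and the intergenic
  complement as annotation tracks;
* an oocyte tract mosaic over whole 100-CpG tiles: hyper (true level
  0.85–0.95), hypo (0.02–0.10) and mid (0.30–0.70) tracts mixed
  0.5/0.2/0.3, with tract lengths of 5 + Geometric(mean 5) tiles — tracts
  are tile-aligned and at least 5 tiles long so planted truth and called
  domains are compared on the same footing;
* sperm at 0.90 everywhere except CpG islands (0.03 in both gametes);
* embryo stages as unphased allele mixtures: the maternal allele retains
  oocyte methylation scaled by stage factors (pig-like preset 0.95 / 0.90 /
  0.85 / 0.18 — a steep morula→blastocyst drop), the paternal allele is
  demethylated fast (0.40 / 0.35 / 0.30 / 0.12); a cow-like preset with a
  shallow decline is included. Presets are qualitative conveniences, not
  claims of equality with any real dataset;
* germline DMRs planted on single tiles of mid tracts (so domain truth and
  imprint truth never interact): 100 maternal and 100 paternal imprinted
  DMRs pinned near 50% in the embryo with a dip at 8–16 cells and recovery
  at the morula (cluster 1: 50/40/50/50) or only at the blastocyst
  (cluster 2: 50/30/32/50), plus 100 + 100 *decoy* gamete-specific DMRs
  that reprogram away like the rest of the genome;
* transient de novo methylation: 30% of hypo tracts gain +20 points at the
  8–16 cell stage only;
* observed counts: depth ~ negative binomial (mean 15, size 5, emulating
  sparse PBAT coverage; 20 in screening checks), methylated calls binomial
  with a symmetric 0.5% conversion error; zero-depth positions are absent,
  as in real coverage files;
* expression: latent log2 FPM = baseline + sd·(r·z + √(1−r²)·ε) with z the
  standardised true gene-body oocyte methylation, so `expr_coupling_r`
  (default 0.4) is the population methylation–expression correlation;
  Poisson fragment counts at a 2 × 10⁷ library.

The planted **domain truth is the segmentation of the noise-free tile
means**, not the raw tract intervals: an unmethylated CpG-island tile
interrupts a hypermethylated tract in truth exactly as it does in a real
oocyte methylome. Raw tracts remain available in `truth$tracts`.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequence-driven CpG density (islands are
rectangles, not observed density profiles), hemimethylation and non-CpG
methylation, bisulfite conversion failure that varies along reads,
replicate-level batch structure, copy-number and mappability artefacts,
and any linkage between repeats and methylation state. Recovery statistics
on this generator certify the *pipeline logic*, not the biology of any
particular dataset.

## Numerical and testing choices

* Random streams are split per phase (genome / methylomes / expression)
  from one mandatory seed; regenerating a study with the same seed is
  byte-identical, and `run_pipeline()` output tables carry a provenance
  header (package version, seed, config hash — no timestamps) so repeated
  runs of the same configuration produce identical files.
* Histogram bins are half-open with a closed last bin, so 100% tiles are
  counted once.
* Ties and boundaries: every threshold comparison is exact and documented
  per operation (inclusive for domains and the intermediate range, strict
  for DMR calling, the delta filter, the demethylation drop and the fold
  change).
* Problem sizes in the shipped checks are chosen to keep the full suite in
  the low minutes on one CPU: genomes of 2–3 chromosomes of 1.5–8 Mb
  (≈ 0.7–2.5 thousand tiles), depths 15–20, 500–1000 replicates for
  type-I calibration, 25 replicates for clustering recovery, and 1000
  replicates for the null-correlation check. Stochastic recovery
  criteria with expectations near their bound (clustering ARI, null
  |r| exceedance) are asserted on replicate means/proportions at the
  unchanged threshold rather than on a single draw, which estimates the
  same quantity with less luck in either direction.
* The trailing `< 100`-CpG remainder of each chromosome is dropped rather
  than forming a short tile, so histograms and domain statistics are never
  biased by unequal windows.

## Known limitations

* Strand collapsing is assumed done upstream (standard coverage-file
  behaviour); the package neither merges nor checks CpG strand pairs.
* The domain run-merging rule is a declared approximation to an
  unpublished segmentation; the gap tolerance exposes its sensitivity.
* The imprint screen is unphased: it finds candidates consistent with
  monoallelic methylation, it cannot prove parent-of-origin behaviour.
* Candidate-to-gene mapping is purely positional (< 50 kb); no
  orthology or external imprinting catalogue is consulted.
* The expression model couples methylation to expression linearly on the
  latent log scale; real coupling is monotone at best.

## A worked run

```{r, eval = FALSE}
library(methrepro)
cfg <- run_config(seed = 1, sim = sim_config(seed = 1), outdir = "run1")
bundle <- run_pipeline(cfg)
report(bundle)
```

See the README for the numbers this prints and how to reproduce the
package's acceptance quantities with `scripts/acceptance.R`.
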