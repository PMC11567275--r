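---
title: "Dual-source profiling of gut bacterial and viral populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-source profiling of gut bacterial and viral populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualvirome)
```

## The problem

Viral-like-particle (VLP) metagenomes sequence the encapsidated, free-virion
fraction of a gut sample, so they see phages in the lytic stage only.
Whole-microbial ("bulk") metagenomes sequence everything — bacterial
genomes, the prophages integrated in them, and free virions — but viral
reads are a small minority of the library. `dualvirome` implements the
analysis layer of a dual-source design that pairs both assays per animal:
validating putative viral genomes, classifying them as temperate or
virulent, calling presence from breadth of coverage, quantifying
populations, and testing community-level and per-feature hypotheses. A
synthetic community generator reproduces the statistical structure the
analysis assumes, so every stage is testable without sequencing data.

## The viral catalog

Putative viral genomes (from binned bulk contigs, unbinned bulk contigs and
VLP assemblies, with external predictor and completeness estimates attached
as input columns) pass through a fixed cascade:

1. **Completeness filter** — keep genomes with completeness ≥ 50% and
   contamination < 10% (`filter_completeness()`; the completeness bound is
   inclusive, the contamination bound strict, following the rule's wording).
2. **Dereplication** — greedy clustering in descending length order into
   species-level representative genomes (SRGs): a contig joins a
   representative when a containment alignment covers 100% of the shorter
   sequence at ≥ 99% identity (`dereplicate()`). The implementation seeds
   candidate alignments with exact 21-mers and extends ungapped along the
   shared diagonal; identity is matches over the aligned span. Equal-length
   ties go to the lexicographically smallest contig id, so output order is
   deterministic. A full local alignment is kept as the test oracle for
   this shortcut.
3. **Validation** — an SRG must be flagged by at least one phage predictor,
   encode ≥ 1 structural protein (terminase, capsid, tail,
   N-acetylmuramoyl-L-alanine amidase — stored under the single token
   `amidase` — baseplate, prohead, coat, virion), and must not be a
   single-structural-gene contig with more than 100 ORFs
   (`validate_viral()`). The ORF count is the number of annotated genes.
4. **Lifestyle** — temperate if the SRG carries any lysogeny-associated
   gene (integrase, transposase, recombinase, Cro/CI domain) *or* shows
   host homology flanked by bacterial regions; otherwise virulent
   (`classify_lifestyle()`). Cro/CI alone is treated as sufficient.

## Presence and abundance

Presence is called from `samtools coverage`-style summaries
(`call_presence()`): a viral SRG is detected when ≥ 70% of its length or at
least 5,000 bp is covered; a bacterial SRG when ≥ 70% or at least
100,000 bp is covered. Both cutoffs are inclusive. Raw abundance is the
rounded mean depth (half away from zero — the least surprising reading of
"rounded"), and features detected in at least 3 samples are retained
(`build_feature_table()`). The prevalence filter is applied within one
assay, since bulk and VLP profiles are built separately.

Gene-level profiling differs deliberately: an ORF is detected only when its
length coverage is *strictly above* 70% (the gene rule is worded "higher
than"), per-ORF abundance is the mean depth, and abundances of ORFs sharing
a gene identifier are summed before integerisation (`profile_genes()`).
Short-chain fatty acid (SCFA) capacity is summarised by summing relative
abundances of fixed KEGG orthology sets for acetate, butyrate and
propionate (`scfa_gene_groups()`, `scfa_totals()`); genes appearing in two
sets (e.g. K01895, K01913, K00925) contribute to both.

Relative abundances divide each sample by the sum over that table's
retained features — a compositional treatment; all-zero samples are kept at
zero and flagged.

## Depth saturation

`thin_coverage()` emulates read subsampling at the coverage level: mean
depth scales linearly and breadth follows the Lander–Waterman expectation
$1 - e^{-\lambda}$ at the thinned depth, with binomial noise on covered
positions, never exceeding the original breadth. This avoids per-base read
simulation while retaining stochasticity. Depths are paired-end read
counts; base conversion uses 2 × read length. `rarefaction_curve()` counts
recovered SRGs over the grid (bulk: 1–25 M PE reads; VLP: 1–15 M; three
replicates), and `detect_plateau()` reports the smallest depth after which
every consecutive increase stays below `epsilon` (default 0.02) times the
final count — the plateau in the original analysis was judged by eye, so
the tolerance is explicit and configurable here. `capture_fraction()`
computes, per breadth threshold and bulk depth, the percentage of the
VLP-derived catalog recovered in the bulk assay; the five default
thresholds {10, 25, 50, 70, 90}% bracket the adopted 70% operating point.

## Community statistics

All permutation machinery is implemented directly and cross-checked against
vegan in the test suite:

- **Alpha diversity**: observed richness, Chao1 ($S + F_1^2/2F_2$, with the
  bias-corrected fallback $S + F_1(F_1-1)/2$ when $F_2 = 0$), ACE (standard
  rare-threshold-10 estimator), Shannon (natural log, the vegan/phyloseq
  default) and Simpson ($1-\sum p^2$).
- **Bray–Curtis** $d_{ij} = \sum|x-y| / \sum(x+y)$, with the distance
  between two all-zero samples defined as 0 and flagged.
- **PCoA** by Gower double-centering and eigendecomposition. Negative
  eigenvalues are dropped (no Cailliez correction) and their count
  reported — the simplest defensible default.
- **PERMANOVA** (`permanova()`): Anderson's pseudo-F from total and
  within-group sums of squared distances; p by label permutation with the
  observed statistic included, $p = (b+1)/(B+1)$, so p is never 0. With
  `exhaustive = TRUE` all distinct two-group assignments are enumerated
  (for a balanced 4 + 4 design there are $\binom{8}{4}/2 = 35$, so the
  smallest attainable p is $1/35 \approx 0.029$ — the floor any study of
  this size runs into).
- **Procrustes** (`procrustes_test()`): symmetric superimposition (both
  configurations centred and unit-trace scaled on their common axes),
  $m^2 = 1 - (\sum \sigma_i)^2$ from the singular values of the
  cross-product, $r = \sqrt{1 - m^2}$, p by row permutation.
- **Test selection** (`group_compare()`): Shapiro–Wilk on residuals and
  Levene's test gate (α = 0.05) between t-test/ANOVA + Tukey and
  Wilcoxon–Mann–Whitney / Kruskal–Wallis + Dunn. Wilcoxon uses the exact
  distribution when sample sizes permit and no ties exist; fully tied data
  returns p = 1. Dunn's test is implemented as rank-sum z statistics with
  tie correction.

## Consensus differential abundance

Three independent simplified engines re-implement the model families of the
standard tool trio rather than wrapping the packages, since planted-truth
recovery — not numeric identity with any one tool — is the validation
target:

- `nb_wald()`: median-of-ratios size factors, method-of-moments negative
  binomial dispersion (floor $10^{-8}$), log2 fold change of group means
  with pseudo-mean 0.5, Wald z test.
- `lm_logtss()`: total-sum scaling, log2 with half-minimum pseudo-fraction,
  equal-variance two-group linear model.
- `css_moderated()`: cumulative-sum scaling at the 50th percentile of each
  sample's positive counts (re-referenced to the median factor),
  log2(x + 1), moderated t with variance shrunk halfway toward the
  across-feature mean variance. The "pooled" degrees of freedom are
  $2(n_1+n_2-2)$ — residual df plus an equally weighted prior, matching
  the 0.5 shrinkage weight.

A feature is a consensus call when all three engines are significant after
per-engine Benjamini–Hochberg correction (q < 0.05) and the NB-engine
|log2FC| exceeds 2 (`consensus()`, `da_consensus()`). The fold change is
taken from the NB engine alone, mirroring the convention of reporting the
DESeq-family estimate.

## The synthetic community generator

`community_config()` / `simulate_experiment()` emulate a two-arm mouse
study (4 mice per group, paired bulk + VLP assays; bulk 20 M and VLP 15 M
PE reads of 150 bp by default — the depths at which recovery saturates):

- 30 bacterial species with lognormal base abundances (sd 1.5 natural log),
  each carrying a small gene complement from a KEGG/CAZyme vocabulary.
- 60 temperate phages, each integrated in a host genome (one copy by
  default — the simplest model of a prophage replicating with its host) and
  released as virions at an induction rate of 0.001 of host abundance;
  25 virulent phages with free-virion abundances around 0.3 of the typical
  host cell scale (log-sd 0.8). These rates place temperate mass above
  virulent mass in bulk and reverse the ranking in the VLP fraction, the
  regime observed in mouse gut data; induction rates are free parameters of
  the model, documented here, not claimed to match mouse biology.
- Abundances are converted to sequence-mass fractions (abundance × genome
  length), so an integrated prophage attains exactly its host's read
  depth. Coverage follows the Lander–Waterman model with binomial noise.
- 0.5% of VLP reads are residual bacterial DNA, stressing the presence
  thresholds the way imperfect VLP preps do.
- **Inter-mouse noise** is hierarchical with total sd 0.8 (natural log):
  75% of the variance is a mouse-level scale factor shared by all taxa
  (litter/load effects, which cancel in relative abundance) and 25% is
  independent per-taxon noise (sd 0.4). A fully independent per-taxon
  sd of 0.8 would swamp a 16-fold effect at n = 4/group and make group
  effects undetectable by any method; the hierarchical split is both the
  more realistic structure for co-housed mice and the one under which a
  planted effect of the stated size is recoverable.
- The `"fiber"` scenario plants a +4 log2 fold change on 10% of bacteria
  (fiber responders, which also carry GH43 and acetate/butyrate genes) and
  on their prophages, and −4 on three virulent phages — the direction
  pattern reported for high- vs low-fiber interventions. The `"angii"`
  scenario plants nothing and serves as the null.

What the generator does **not** emulate: assembly and binning errors,
strain-level microdiversity, read-level sequencing error, chimeric contigs,
compositional interactions beyond closure, and any real taxonomy. Passing
tests therefore demonstrate that the pipeline recovers structure *of the
kind it assumes*, at the study's design size — not that it is robust to
every artefact of real metagenomes.

## Numerical conventions and degenerate inputs

- Rounding of depths and percentage formatting: half away from zero;
  percentages are reported to one decimal.
- Permutation p-values always include the observed statistic and report the
  permutation count.
- Empty samples give diversity 0 with a warning; empty catalogs and empty
  coverage inputs propagate as empty results, not errors; duplicate
  (feature, sample) coverage records are an error.
- All randomness flows from a single integer seed through per-stage derived
  streams, so every pipeline product — including the run report JSON — is
  bit-for-bit reproducible.

## Problem sizes used by the test suite

The suite validates calibration with 500 null simulations per engine at
n = 4/group (plus 500 at n = 10/group for PERMANOVA, where the permutation
distribution is rich enough to support the nominal 0.05 level), planted
recovery over 50 simulated studies, ordination coupling over 20, lifestyle
asymmetry over 20, and saturation on a single deep sample (≈28.4 M bulk /
19.4 M VLP PE reads). These sizes give binomial standard errors small
enough to check the stated tolerances while keeping the default test run
quick on one CPU.

## Limitations

- The classifier inherits the known failure modes of marker-based lifestyle
  calls: fragmented genomes missing their integrase, novel lysogeny
  mechanisms, and marker genes with other functions are all misclassified.
- The DA engines are deliberate simplifications of their model families;
  they are validated against planted truth, not against the reference
  implementations' numbers.
- With 4 animals per group, permutation tests cannot produce p below
  1/35 (two-group balanced design); results at this size are floor-limited
  by design, not by implementation.
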