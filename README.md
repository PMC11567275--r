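# dualvirome

Dual-source (bulk + VLP) metagenomic profiling of gut bacterial and viral
populations.

## What it is for

Viral-like-particle (VLP) metagenomes capture only the free-virion, lytic
fraction of a gut virome and miss prophages — the intracellular state in
which most gut temperate phages reside. Whole-microbial ("bulk")
metagenomes capture bacteria, integrated prophages and virions together,
but viral reads are a small minority of each library. `dualvirome` is an R
package for analysing paired bulk + VLP designs end to end:

- **Viral catalog construction** — completeness/contamination filtering
  (≥ 50% complete, < 10% contaminated), greedy dereplication into
  species-level representative genomes (SRGs) at 99% identity over 100% of
  the shorter sequence, validation by phage-predictor flags and structural
  genes, and temperate/virulent classification from lysogeny markers
  (integrase, transposase, recombinase, Cro/CI) or host-flanked homology.
- **Abundance profiling** — breadth-of-coverage presence calls (viral:
  ≥ 70% breadth or ≥ 5,000 bp covered; bacterial: ≥ 70% or ≥ 100,000 bp),
  rounded-mean-depth abundances, a ≥ 3-sample prevalence filter, gene
  profiles with a strict > 70% ORF rule, and SCFA gene-group totals.
- **Depth saturation** — coverage-level rarefaction under the
  Lander–Waterman model (breadth = 1 − e^(−λ)), plateau detection, and the
  breadth-threshold × depth grid of VLP-catalog capture in bulk.
- **Community statistics** — alpha diversity (observed, Chao1, ACE,
  Shannon, Simpson), Bray–Curtis distances, PCoA, PERMANOVA (pseudo-F,
  permutation p with exhaustive enumeration for small designs), Procrustes
  randomization tests, a Shapiro–Wilk/Levene-gated group comparison rule,
  and FDR-corrected correlation batches.
- **Consensus differential abundance** — three independent engines
  (negative-binomial Wald with median-of-ratios normalisation; log-TSS
  linear model; CSS-moderated t) combined by the conservative consensus
  rule: all three FDR-significant *and* |log2FC| > 2.
- **Synthetic communities** — a generator that emulates the paired-assay
  mouse-gut design (lognormal bacteria, host-tracking prophages with a
  small induction rate, free virulent virions, planted diet effects), so
  the whole pipeline is testable against known ground truth.

Functions take tibbles and return tibbles; results chain with the pipe, and
fitted objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
figures.

## Worked example

Simulate a high- vs low-fiber intervention (4 mice per group, paired
bulk + VLP assays) and run the full pipeline:

```r
library(dualvirome)
report <- run_experiment(community_config(scenario = "fiber"),
                         seed = 2, n_perm = 199)
print(report)
#> Dual-source virome run report
#>   scenario: fiber, seed 2
#>   viral catalog: 85 SRGs (60 temperate, 25 virulent)
#>   bacterial_bulk: PERMANOVA R2 = 0.790, p = 0.05
#>   viral_bulk: PERMANOVA R2 = 0.783, p = 0.02
#>   viral_vlp: PERMANOVA R2 = 0.347, p = 0.035
#>   Procrustes viral~bacterial: r = 0.997, p = 0.005
#>   consensus DA (bacterial_bulk): 3 feature(s)
#>   consensus DA (viral_bulk): 7 feature(s)
```

Reading the output: all 85 simulated phages pass the validation cascade and
keep their planted lifestyles (60 temperate, 25 virulent). Diet explains
most of the between-sample Bray–Curtis variance in the bulk tables
(R² ≈ 0.78–0.79) at the smallest p this 4 + 4 permutation design can
produce, the viral ordination mirrors the bacterial one almost perfectly
(Procrustes r ≈ 1), and the consensus rule calls 10 differentially
abundant features — the planted fiber responders and their prophages.

The same run is available from a shell:

```sh
Rscript inst/scripts/virome-pipeline.R --scenario fiber --seed 2 --outdir out/
```

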