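---
title: "Methods: pan-genome PAV analysis with panpav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome PAV analysis with panpav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panpav)
```

## Scope and model

`panpav` analyses gene presence/absence variation (PAV) in a crop
pan-genome across three domestication-improvement stages — in the cotton
nomenclature it was written around: landraces, improved cultivars bred in
the USA and other countries (GhImpUSO), and improved cultivars bred in
China (GhImpCHN). The pipeline has five analytical layers:

1. **Variant retention.** From diploid genotypes, the "core variation" set
   retains biallelic SNPs with minor allele frequency at least 0.01
   (computed over non-missing alleles, the VCFtools/PLINK convention),
   missing rate at most 0.8, and at least 5 accessions homozygous for the
   alternate allele; InDels are capped at 20 bp. "Homozygote" is read as
   homozygous-alternate: a reference-homozygote criterion would be vacuous
   for rare variants.
2. **Diversity scan.** Windowed nucleotide diversity
   $\pi_w = \sum_{s \in w} \hat\pi_s / L_w$ with the per-site estimator
   $\hat\pi_s = 2 j (n - j) / (n (n - 1))$ for $j$ alternate among $n$
   observed alleles; monomorphic sites contribute zero implicitly through
   the full-window-length denominator $L_w$ (the `--window-pi`
   convention). Selection regions are windows with
   $\pi_\text{earlier} / \pi_\text{later} \ge$ a threshold (15 for the
   landrace-vs-improved "domestication" contrast, 2 for the
   GhImpUSO-vs-GhImpCHN "improvement" contrast), optionally intersected
   with the top 5% of an externally computed likelihood score track
   (e.g. XP-CLR), then merged across gaps up to the window step.
   Weir & Cockerham (1984) weighted $F_{ST}$
   ($\sum a / \sum (a + b + c)$ over usable sites) is computed alongside.
3. **PAV calling and classification.** A gene is present in an accession
   when strictly more than 80% of its exonic bases are covered by at
   least `min_cov` = 2 reads. With presence count $c$ among the $N$
   high-depth accessions (mean depth $\ge$ 5): core iff $c = N$; softcore
   iff $\lceil 0.97N \rceil \le c \le N - 1$; cloud iff
   $1 \le c \le \lfloor f_\text{cloud} N \rfloor$ (1% default, 2% for
   small panels); shell otherwise. Genes seen only in low-depth
   accessions are singletons and excluded from frequency analyses.
   Saturation curves track the cumulative union (pan) and intersection
   (core) of gene sets over random accession orderings.
4. **Selection of PAVs.** Per gene and stage, a two-sided Fisher's exact
   test on the presence/absence counts of the two groups, BH-FDR
   corrected within the stage; a verdict requires FDR < 0.001 and a
   frequency fold change (earlier/later) outside [0.5, 2] — below 0.5 the
   gene rose in frequency ("favorable"), above 2 it fell ("unfavorable").
   Frequency paths across the three groups are classified by strict
   inequality chains into favorable/unfavorable gain/loss.
5. **Association and QTL overlap.** A PAV's presence vector is tested
   against each SNP with a 2x2 allelic Fisher test; SNPs passing the
   Bonferroni threshold $\alpha / N$ are intersected with QTL intervals.

All internal coordinates are 0-based half-open; VCF and GFF3 1-based
conventions are converted at the I/O boundary only. Interval algebra
(merging, intersection, overlap) is delegated to
IRanges/GenomicRanges behind the `region_set` surface.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `maf_min`, `missing_max`, `min_hom_accessions` | 0.01, 0.8, 5 | — | the core-variation retention cascade |
| `window_size`, `step` | 100 kb, 20 kb | bp | the scan grid; a 1 Mb / 200 kb grid is equally valid for coarse genome-wide views and both are exposed |
| `ratio_min` (domestication / improvement) | 15 / 2 | — | diversity-ratio selection thresholds |
| `top_q` | 0.05 | — | upper quantile of the external score track |
| `presence_fraction` | 0.8 (strict `>`) | fraction | exonic-coverage presence cutoff |
| `lost_cutoff` | 0.2 | fraction | lower edge of the ambiguous coverage zone |
| `low_depth_threshold` | 5 | mean depth | accessions below it cannot support absence calls |
| `softcore_min_fraction`, `cloud_max_fraction` | 0.97, 0.01 (0.02 small panels) | fraction | class boundaries |
| `fdr_max`, `fc_bounds` | 0.001, (0.5, 2) | — | selection verdicts |
| `alpha` | 0.05 | — | Bonferroni family-wise rate for association |

Three numerical choices deserve emphasis because the canonical boundary
ranges pin them down exactly:

* the softcore lower bound uses a **ceiling** and the cloud upper bound a
  **floor** — the only rounding pair consistent with softcore 990–1019 and
  cloud 1–10 at $N = 1020$, and shell 4–171 at $N = 177$ with a 2% cloud
  fraction;
* the presence rule is **strict** at 0.8: exactly 80% covered is absent.
  The gray zone between `lost_cutoff` and `presence_fraction` is counted
  and reported but treated as absence, since the calling convention
  defines presence only above 80%;
* for small panels the 0.97 softcore fraction (not 0.98) is the value
  consistent with the 172-of-177 softcore boundary, and is therefore the
  default for both panel sizes.

Other conventions for degenerate inputs: a window ratio with zero
denominator and positive numerator is $+\infty$ (complete diversity loss
in the later group — selected, but counted separately); windows with both
$\pi$ zero are uninformative and never selected. A fold change with zero
later-stage frequency is likewise $+\infty$ and qualifies as $> 2$; genes
absent from both stage groups are untested. Ties at the top-quantile score
cut are all included (deterministic and inclusion-conservative). Ties in
trajectory chains give "none". BH correction is applied per stage, not
across stages, because the two contrasts are reported separately.

## The synthetic-data generator

Real re-sequencing inputs for this analysis are terabyte-scale, so the
package ships a generator ([simulate_genotypes()], [simulate_gene_content()],
[simulate_phenotype()]) that reproduces the *statistical* structure the
pipeline assumes, together with truth tables for recovery testing.

* **Genotypes.** Sites are independent (no linkage). Each site has an
  ancestral allele frequency drawn uniformly on (0.05, 0.95); each group
  keeps the same major-allele side but its expected heterozygosity is
  scaled by a per-group factor — default 1 / 0.35 / 0.31 for
  landrace / GhImpUSO / GhImpCHN, the ratios of representative
  nucleotide-diversity estimates ($1.07\times10^{-3}$,
  $3.74\times10^{-4}$, $3.34\times10^{-4}$). Inside a planted sweep
  window the improved groups' heterozygosity is further divided by the
  window's factor. Genotypes are Hardy-Weinberg binomial draws with 2%
  missingness. Sweeps are therefore modelled exactly at the level the
  ratio detector measures, not as coalescent trajectories.
* **Gene content.** Class composition defaults to representative
  proportions scaled to a 400-gene catalogue (247 core / 23 softcore /
  15 shell / 48 cloud / 67 singleton). Softcore/shell/cloud presence
  counts are drawn uniformly within their class ranges over high-depth
  accessions; 35% of accessions are low-depth (561 of 1581 in the panel
  this emulates); singletons occupy 1–3 low-depth accessions. Stage-selected
  genes take explicit per-group frequencies whose implied fold change
  must exceed 2 or fall below 0.5. There is no generative model of PAV
  origination in the source analysis, so this class-composition planting
  is the package's own construction.
* **Coverage.** Conditional on true presence, the covered exonic
  fraction is Beta(40, 2) (mean 0.95); conditional on absence,
  Beta(2, 40). Both place most mass cleanly across the 0.8 cutoff while
  leaving a small, testable gray zone; the implied miscall probability is
  about 0.1% per present gene and numerically zero per absent gene.
* **Phenotype.** `effect * presence + N(0, sd)` for one designated PAV.

What the generator does *not* emulate — linkage disequilibrium, population
substructure within groups, mapping artefacts, reference bias in coverage,
depth-dependent calling error — bounds what green tests mean: they show
the estimators and decision rules are implemented correctly and recover
planted signals at the intended operating points, not that the pipeline is
robust to every property of real re-sequencing data. In particular the
PAV-SNP association is deliberately unstructured (plain allelic Fisher
test); on structured populations it will produce inflated hit counts
relative to a mixed-model analysis, and its outputs are intended for
threshold bookkeeping and QTL overlap.

## Problem sizes used by the test-suite

The recovery suites run at desk scale, chosen to keep the full test run in
a few minutes while leaving comfortable statistical margins: sweep
recovery uses one 2-Mb chromosome, 1000 SNPs, the full 256/438/929 group
sizes and 200 seeds (two planted factor-20 sweeps of 200 kb); selection
recovery and the null cohort use the reference PAV panel sizes
182/206/592 with 160–250 background genes and 200 seeds; the exhaustive
Fisher cross-check covers every 2x2 table with total at most 40
(~132,000 tables). The law-of-large-numbers check on planted frequencies
uses 2000 accessions per group.

## Known limitations

* Frequencies, not counts, define fold changes (group sizes differ); a
  count-based definition would shift genes near the boundary.
* The improvement scan tests only diversity loss in the later group
  (GhImpUSO/GhImpCHN ratio above threshold), mirroring the stated
  contrast; the reverse direction is not scanned.
* Saturation sampling defaults to 200 orderings x 5 replicates; the
  split between "orderings" and "replicates" only affects batching, and
  both knobs are exposed.
* `read_vcf_genotypes` keeps the first alternate allele's dosage only;
  multi-allelic sites are flagged for exclusion rather than decomposed.
* Half-calls (e.g. `./1`) are read as missing.
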