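---
title: "Measuring Z-chromosome dosage compensation: methods and design notes"
author: "zdosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring Z-chromosome dosage compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zdosage)
```

## The problem

In female-heterogametic (ZW) species such as the silkworm *Bombyx mori*,
males carry two Z chromosomes and females one. Absent regulation, the
average Z-linked transcript would therefore be ~2-fold male-biased. Dosage
compensation (DC) is the regulatory equalization of this difference, and
two population-level estimates diagnose it from RNA-seq:

1. **Z:A ratio** — within a sample, average Z-linked expression divided by
   average autosomal expression. Computed both mean-based and median-based
   on the linear FPKM scale, over the "true expression" gene set
   (FPKM ≠ 0 in that sample). A value of 1 means Z-linked genes run at
   autosomal level; 0.5 means half of it. In *B. mori* the interesting
   regime is Z:A ≈ 0.4–0.65 *in both sexes* — equalized between sexes but
   below autosomes, i.e. compensation achieved by reduced ZZ expression in
   males rather than hyperactivation of the single female Z.
2. **M:F ratio distribution** — per gene expressed in both sexes,
   M:F(g) = male FPKM / female FPKM. The class medians
   (median M:F over Z-linked genes, over autosomal genes) and their
   quotient, the *Z:A ratio of medians*, summarize sex bias at the
   chromosome level; ≈1 indicates the Z is no more sex-biased than
   autosomes. Three Mann–Whitney tests accompany each stage: male vs
   female within the Z class, within the A class, and Z vs A on the
   log2-ratio distributions.

`zdosage` implements both estimates plus their supporting machinery, and a
simulator that generates count data with known dosage truth so every stage
of the pipeline is testable without sequencing data.

## Pipeline and its conventions

`runDosageAnalysis()` executes, in order: read inputs → chromosome linkage
→ FPKM from counts → technical-replicate averaging → true-expression
filtering → Z:A summaries + bootstrap CIs → M:F summaries under FPKM and
TMM normalization → quartile reports → Z-profile export. Conventions worth
stating explicitly:

- **Units.** FPKM(g, s) = 10⁹ · count / (length · library size). Gene
  length is the merged-isoform (union) length when derived from
  annotation, else a supplied `gene_length` column. Any upstream
  contamination-correction step of the original quantitation tool is not
  modeled: the downstream statistics depend only on relative expression.
- **Medians on the linear scale.** All reported means/medians and their
  ratios are linear-FPKM quantities; log2 values are used only as test
  inputs and plot axes. For odd-length vectors the two agree after
  back-transformation (the median commutes with monotone maps); for
  even-length vectors they differ (arithmetic vs geometric mean of the
  central pair) and linear is authoritative.
- **No pseudocounts.** log2 is only ever taken after the true-expression
  filter removes zeros. The profile export (`zProfileMatrix`) is the one
  deliberate exception: it keeps silent Z-linked genes and floors zeros at
  2⁻¹⁰ (a log2 value of −10), for display only.
- **Filters.** Z:A uses the per-sample positive gene set; M:F uses genes
  positive in both the male and female column of a stage. The TMM branch
  additionally removes genes with fewer than `min_count = 4` raw reads in
  any one of the stage's four libraries (2 male × 2 female technical
  replicates); a count of exactly 4 survives. Both filters are idempotent.
- **Chromosome linkage.** Genes are mapped to chromosomes via the scaffold
  they reside on (GFF3 `gene` features keyed on `ID`; the feature type
  choice is a documented reading — loci are expected to appear once after
  isoform merging). Scaffolds absent from the map become `"unplaced"` and
  are dropped from analysis, not errors. The Z chromosome number is a
  parameter (`z_chromosome`, default 1 for *B. mori*); the annotation
  carries no W chromosome, so any such label would also be dropped.

## Statistical components

**Mann–Whitney U** (`mwuTest`). U counts pairs with x > y, ties counting
half. When min(n₁, n₂) ≤ 8 the p-value is exact: from the exact Wilcoxon
distribution when the pooled sample is tie-free, or by full enumeration of
all group assignments over the observed midranks when ties are present.
The two-sided exact p doubles the smaller tail, capped at 1 — so two
identical samples give p = 1 exactly, which a normal approximation with
continuity correction would not. (The "and no ties" proviso for exactness
was dropped deliberately: enumeration over midranks is exact conditional
on the observed ties and keeps the symmetric-inputs case clean.) Larger
samples use the normal approximation with tie and continuity corrections.
p-values are reported raw; the analysis applies no multiple-testing
correction by design, since each table cell is a distinct planned
comparison.

**TMM normalization** (`tmmFactors`). Between-sample scaling factors from
the weighted trimmed mean of M-values, over genes positive in both
libraries: trim the top/bottom 30% by log-ratio M and top/bottom 5% by
average intensity A (intersection of survivors; rank-based with average
ranks on ties), weight survivors by inverse delta-method variance, and
rescale all factors to geometric mean 1. The trim fractions are the
method's canonical defaults — the analysis this package reproduces names
the method but not its settings, and the defaults are recorded in the run
manifest. The reference sample defaults to `"auto"`: the sample whose
75th-percentile count fraction is closest to the mean of those fractions.
If no gene survives trimming the factor falls back to 1 with a warning;
a sample sharing no expressed gene with the reference is a hard error.

**Bootstrap CI** (`bootstrapZaMedian`). The median-based Z:A ratio gets a
percentile bootstrap: each of `n_boot = 10000` replicates resamples the A
and Z vectors independently (each within its own class, at its own size,
with replacement) and recomputes the ratio of medians. Independent
within-class resampling is the only scheme consistent with a statistic
that is a ratio of two group medians. The reported point estimate is the
*median of the bootstrap distribution* — deliberately, because the
published bootstrap medians differ slightly from the plug-in ratios,
indicating the original tool summarized the bootstrap distribution — and
the interval is the empirical 2.5/97.5 percentile pair with linear
interpolation. Resampling is on the linear scale; for odd resample sizes
this is identical to bootstrapping logs and back-transforming. Everything
is reproducible from an explicit integer seed, and the suite verifies
92–98% empirical coverage for a known ratio of medians of 0.5.

**Quartile stratification** (`independentQuartiles`,
`pairedMaxQuartiles`). To check that a dosage pattern holds at all
expression magnitudes, genes are split into quartiles Q4 (high) … Q1
(very low): either each sex sorted and binned independently, or — for the
paired M:F universe — gene pairs ranked by max(male, female) so a gene's
two values never separate. Sorting is descending with ties broken by gene
id (reproducibility); when n is not divisible by 4 the remainder goes to
the higher-expression bins first (a near-equal contiguous split; the
source analysis never states its rule, and this is the least surprising
one). Bin membership is invariant to any order-preserving transform, so
binning on FPKM or log2 FPKM is equivalent; per-bin medians are reported
on log2 FPKM, matching the usual plot axis.

**Profile export and clustering.** `zProfileMatrix` exports all Z-linked
genes (silent ones floored, see above). `clusterGenes` offers
deterministic average-linkage clustering on correlation distance with
canonicalized labels (clusters numbered by their lexicographically
smallest member, so labels are invariant to row order). The cluster count
is a user parameter: the published ten-cluster heatmap came from an
unnamed algorithm with unstated settings, and reproducing its exact
clusters is explicitly not attempted.

**ΔCt fold change** (`deltaCtFold`). For qRT-PCR validation:
fold = 2^(−ΔΔCt) against a reference gene with the female sample as
calibrator, so female ≡ 1 and a male-biased gene gives fold > 1.

## The simulator: what it emulates, and what it does not

`generateDataset` draws counts(g, s) ~ NegBin(mean, size = `dispersion`)
with mean = library-size-scaled gene baseline × class/sex/stage factors:

- ~450 Z-linked genes (chromosome 1) and ~9600 autosomal genes
  (chromosomes 2–28), matching the annotated gene census scale;
- gene baselines 2^Normal(3, 2) (a realistic right-skewed FPKM
  distribution spanning ~4 orders of magnitude) and lengths
  LogNormal(log 1500, 0.5) bp;
- NB size 10 (biological-scale overdispersion, CV ≈ 33% at high counts),
  library size 10⁷, two independent technical replicates per sample;
- 5% of genes silent per sex (drawn per gene × sex, shared across stages),
  yielding the observed ~10 000 expressed genes per embryonic sample;
- per-stage dose factors d_male, d_female on Z-linked genes (the reduced
  Z:A baseline acts in both sexes) and a male bias b_s.

One design point deserves emphasis. A male bias applied uniformly to
*every* gene is invisible in relative expression data: FPKM divides by
the library total, which scales by the same factor, so the bias cancels
identically. The generator therefore applies b_s to the lower-expressed
`biasedFraction` of genes (default 80% by number — which, under the
heavy-tailed baseline, hold only ~30% of read mass), leaving the few
top-expressed genes as an unbiased read-mass reservoir, and solves the
applied factor exactly so that a biased gene's expected
library-normalized M:F equals b_s. The median gene of each class is then
biased by construction and the `simTruth` contract (A M:F = b_s, Z M:F =
d_m·b_s/d_f) holds for the observed statistics. Biologically this mirrors
the common situation where sex bias sits in the many moderately expressed
genes while the highest-expressed housekeeping genes are unbiased. Two
consequences: with NB noise the sample median of the 80/20 mixture is
pulled slightly toward 1 (the parameter-recovery tests allow for this),
and TMM — whose trimmed mean absorbs a majority-gene shift — removes part
of b_s, so FPKM- and TMM-based M:F agree in direction but not magnitude
when b_s ≠ 1.

The presets are stated worlds, not tuning knobs: `uncompensated_early`
(b = 1.35, d = 0.5/0.45 → Z M:F truth 1.5, the early-embryo state),
`compensated_head` (b = 1, d = 0.6/0.6 → truths 1.0 and Z:A 0.6), and
`bombyx_like_timecourse` (four stages with Z M:F truth 1.5 → 1.4 → 1.1 →
1.0, a stylized monotone relaxation into compensation — the real time
course is not monotone at 78 h, where overall Z expression is still low).
The null-configuration type-I-error check uses 2000 autosomal + 450
Z-linked genes per replicate over 200 seeds, a size chosen for runtime;
the nominal-size property does not depend on gene count.

What the simulator does **not** emulate: read-level artifacts (mapping
bias, positional coverage), gene–gene correlation, batch structure beyond
technical replicates, or a W chromosome. A green parameter-recovery test
therefore establishes that the pipeline's estimators are consistent for
the statistical structure assumed — not that any particular biological
dataset satisfies those assumptions.

## Numerical and degenerate-input choices

- Exact MWU enumeration is limited to min(n₁, n₂) ≤ 8, where the
  assignment count stays tractable; beyond that the tie-corrected normal
  approximation is standard practice.
- Bootstrap quantiles use R's default type-7 linear interpolation;
  constant inputs give a zero-width interval at the exact ratio.
- `zaSummary`/`mfRatios` refuse zeros and empty vectors rather than
  silently filtering: the true-expression filter is an explicit pipeline
  stage, not a hidden default.
- TMM on a sample pair with identical or exactly genewise-scaled
  libraries returns factors of exactly 1 (the library-size term absorbs
  any common scaling); factors are invariant to scaling a whole library.
- Quartile and clustering tie-breaks are by gene id, making every output
  table byte-reproducible under a fixed seed (verified in the suite).
- Technical-replicate averaging is the arithmetic mean of FPKM, applied
  before all filters and statistics; singleton groups pass through.

## Limitations

The package analyzes expression matrices; read QC, trimming and alignment
are upstream and out of scope. The M:F rank-sum comparisons are unpaired
distribution-level tests (matching the source analysis), not paired
per-gene tests, so they are conservative for detecting small coherent
shifts. Mean-based Z:A ratios are dominated by the expression heavy tail
and are noisier than median-based ones at realistic gene counts — both
are reported, but median-based values carry the interpretation. Bootstrap
intervals are percentile (not BCa) by design, matching the original
tooling's behavior.
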