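---
title: "Mapping natural variation across miRNA substructures: models and design"
author: "mirvarmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping natural variation across miRNA substructures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirvarmap)
```

# The problem

A microRNA precursor is a hairpin from which one or two ~22-nt mature
products are excised.  Function concentrates unevenly along the hairpin:
the *seed* (mature positions 2–8) drives target recognition, the rest of
the mature sequence and the loop matter for processing, and the flanking
arms are the most tolerant.  A population map of miRNA variation therefore
needs (i) an exact, strand-aware decomposition of each precursor into these
substructures, (ii) per-variant cohort statistics, (iii) checks for sites
whose genotype proportions suggest selection, and (iv) structure-aware
summaries across populations, diseases and pathways.  `mirvarmap`
implements that chain on standard file formats, with a synthetic cohort
generator providing ground truth for every stage.

# Substructure decomposition

All coordinates are 1-based inclusive; GFF3 and VCF agree on this
convention, so no conversion happens at any interface (BED export is the
single exception and is converted on write).  Work happens in *transcribed*
coordinates (1..L from the hairpin's 5' end), so a minus-strand precursor
yields the same label sequence as its plus-strand mirror.

Per annotated mature arm the decomposition is: position 1 →
rest-of-mature (`rom`), positions 2–8 → `seed` (7 nt whenever the arm has
at least 8 nt; shorter arms get a truncated seed with a warning), positions
9..end → `rom`.  The stretch strictly between two arms is the `loop`
(abutting arms simply yield none); everything outside the arms is the `5'
mir` / `3' mir` flank.  The seed deliberately excludes mature position 1:
although some target-recognition models extend the seed to include it, the
2–8 definition is the conventional one and is what the package adopts;
position 1 is rest-of-mature.

**The `(mix)` qualifier.** Annotation frequently lacks one arm (or both).
The star strand of the missing arm is then indistinguishable from flank, so
the whole armless side is labeled `5' mir (mix)` or `3' mir (mix)` — "mix"
because the region mixes putative star-strand and flank sequence.  A
precursor with no mature annotation at all is split at the transcribed
midpoint into a `(mix)` pair.  This is an explicit convention of this
package (recorded in output metadata); whether duplex overhangs belong to
arm or loop is likewise not standardized, and segments between arms are
uniformly `loop` here.

Arm identity (5p/3p) comes from the mature name suffix when present,
otherwise from the transcribed-orientation midpoint rule.  The segments of
each precursor always partition it exactly — the test suite checks this per
base against an independent labeling oracle on fuzzed precursors.

# Variant profiles and conventions

Only biallelic SNVs are profiled; multiallelic records are split into one
record per alternative allele and indels are dropped (counted in the filter
log).  Conventions that matter downstream:

* **Pooled carrier frequency** uses the *full* cohort as denominator
  (carriers / cohort size × 100), so 1 carrier of 1,152 is 0.0868% and 301
  carriers are 26.1285%.  Missing genotypes count as non-carriers here.
* **Zygosity in the Hardy-Weinberg scan** uses the genotyped population as
  total: missing calls are excluded, all genotyped non-carriers are
  hom-ref.  Half calls (`./1`) are treated as missing throughout.
* A variant under several (overlapping) precursors yields one profile row
  per precursor.
* Novelty is allele-aware: a known position with a different alternative
  allele is still novel.
* The mean alternative-allele read fraction is reported over heterozygous
  calls when allelic depths are present; no QC threshold is enforced on it
  (it is a diagnostic, not a filter).

# The Hardy-Weinberg deviation scan

Expected counts \(np^2, 2npq, nq^2\) are computed from the observed allele
frequency; the statistic is \(\sum (\max(|O-E|-c, 0))^2/E\) with one degree
of freedom, where the continuity correction \(c = 0.5\) is **on by
default**: the corrected test is what reproduces published worked examples
of this scan (counts 25/13/22 at n = 60 → p = 2.82e-05; 29/15/17 at n = 61
→ p = 3.03e-04; 76/8/5 at n = 89 → p = 2.23e-05; the uncorrected test gives
~1.2e-05, ~1.4e-04 and ~1.8e-06 on the same counts).  A flag exposes the
uncorrected test.  The correction is capped at \(|O-E|\) so that tiny
deviations cannot inflate the statistic.  Monomorphic counts return p = 1
rather than erroring, keeping scan totals stable.  One published row
(a single-subject population entry printed as p < 1e-15) is not consistent
with any variant of this test on its printed counts; the convention that
reproduces the other rows is used and the discrepancy left documented
rather than resolved.

α defaults to 0.05 with **no multiple-testing correction** — the scan
reports raw p-values, matching how such tables are conventionally printed
(rows up to p ≈ 0.0499); Benjamini-Hochberg is available as an option.
Under null simulation the corrected test is conservative (empirically
~2–3% at α = 5%, n = 100) and the uncorrected test approximately calibrated
(~5%); both are asserted by Monte-Carlo tests at fixed seeds.

# Stratification PCA

Sites are filtered to coverage strictly above 10× (mean depth over a
configurable anchor cohort — which cohort anchors the filter is a runtime
parameter, not hard-coded) and at least one carrier.  Normalization is the
Eigenstrat one: center each site by its mean dosage, scale by
\(\sqrt{\hat p(1-\hat p)}\), mean-impute missing genotypes per site, then
eigendecompose the sample covariance.  \(\hat p\) defaults to the shrunk
estimator \((1+\sum g)/(2+2n)\), which stabilizes the scaling of rare sites
on small cohorts; the plain MLE is a flag away.  Sites with allele
frequency 0 or 1 are dropped (their scaling is undefined); zero-variance
but polymorphic sites (e.g. all-het) are kept and contribute nothing.
Component signs are canonicalized (largest-magnitude coordinate positive),
making results deterministic.

A known limitation: under a *star-shaped* Balding-Nichols model the
contrast between the two least-diverged of four groups is the weakest
eigen-direction and tends to fall on PC3, so k-means on PC1–PC2 recovers
the four groups with adjusted Rand ≈ 0.7–0.98 depending on the draw.  Real
continental cohorts show correlated drift (shared history), which spreads
the groups across the top two components more reliably than the star model
does.  The fixed-seed recovery test uses 4 × 30 samples and 300 sites at
divergences 0.02–0.15.

# Cross-tabulations

Shared-variant matrices count common variant positions (keyed by
chromosome, position and alternative allele) per population pair, over all
sites or seed-only sites.  The population-by-disease matrix counts variant
positions whose miRNA is linked to each disease category — a variant in a
pleiotropic miRNA counts toward every linked category (the
pleiotropy-preserving convention; counting variant-disease pairs instead
would double-count positions within a category).  Disease categories are an
input column, not a hard-coded ontology.  A pathway is "affected" in a
population when at least one of its genes is targeted by a miRNA with a
seed-region variant present there; profiles report the percentage of each
category's pathways affected.  The miRNA→target table is an explicit input;
no target-prediction algorithm is bundled.  Heat-map orderings use
agglomerative clustering on Euclidean distances with complete linkage
(configurable); hive-plot edge lists are emitted for external rendering —
their weights marginalize exactly to the matrix entries, which the tests
assert.

# The synthetic cohort generator

The generator's defaults describe the emulated study conditions: 15
populations in four geographic groups totalling 1,152 samples, 720
precursor hairpins, and 35% of sites absent from the known-id table.
Population divergence follows the Balding-Nichols model — per site an
ancestral frequency \(p_0 \sim \mathrm{Beta}(0.3, 3)\) (rare-skewed, as
observed cohort spectra are), and per population a Beta draw with
divergence F around \(p_0\).  Default F values are 0.02 (EUR), 0.05 (AMR),
0.08 (ASI) and 0.12 (AFR), spanning the range typical of human continental
differentiation.  Genotypes are Hardy-Weinberg within populations except at
planted sites, where an inbreeding coefficient f deflates heterozygosity
(\(P(\mathrm{het}) = 2pq(1-f)\); ten sites at f = 0.5 by default).

Variant placement is per base with region-dependent relative densities —
seed 0.35, rest-of-mature 0.55, loop 0.75, flanks 1.0 — mirroring the
qualitative ordering observed in real precursors (functional regions are
depleted).  The base rate (0.011/base) makes a full-scale cohort yield
roughly 500–650 variant sites, the observed order of magnitude.  African
populations receive a 1.4× site-density multiplier implemented as
group-private extra sites, reproducing their documented burden excess
(~37 vs ~27 variants per individual, a ratio of ~1.35–1.4).  Read depths
are Poisson(40) — the coverage scale reported for exome-derived miRNA
regions — with binomial allelic depths at heterozygous calls.

One modeling point worth recording: under plain Balding-Nichols the
expected per-sample burden at a site is \(2p_0 - p_0^2 - F p_0(1-p_0)\),
which *decreases* with F, so divergence alone cannot produce a
higher-burden group; the density multiplier is the mechanism that does.
Region labels in the truth object come from the same decomposition the
pipeline uses, so truth comparison tests label *consistency* (any
classifier drift breaks the diagonal confusion matrix), not an independent
re-derivation — the independent per-base oracle lives in the test suite.

What the generator does **not** emulate: linkage disequilibrium and
recombination (sites are independent), mutation-rate heterogeneity beyond
the region densities, sequencing error in genotypes, and correlated drift
between populations (the star-model limitation above).  Tests passing on
synthetic data therefore validate bookkeeping, statistical calibration and
recovery of planted structure — not robustness to LD or to batch artifacts
in real call sets.

# Problem sizes and determinism

The test suite runs everything at reduced scale (tens of precursors,
30–200 samples per population) with fixed seeds; Monte-Carlo checks use
2,000–10,000 replicates for calibration and 1,000 for power.  The
acceptance script runs the full emulated scale (1,152 samples × 720
precursors, ~95 s) plus the calibration suites (~2.5 min total).  A fixed
seed makes every emitted file byte-identical across runs; the pipeline
itself is deterministic given its inputs.

# Interfaces

Each stage reads and writes plain TSVs so stages are independently
testable; `runPipeline()` orchestrates them and writes a filter ledger
(records read → SNV-only → in-precursor → profiled), because headline
counts in this kind of study are filter outcomes.  A thin command-line
wrapper (`inst/scripts/mirvarmap.R`) exposes `simulate` and `report`
subcommands over the same functions.
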