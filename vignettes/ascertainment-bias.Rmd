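---
title: "Quantifying marker ascertainment bias between genotyping platforms"
author: "markerbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying marker ascertainment bias between genotyping platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerbias)
```

## The problem

Two genotyping platforms assay the same inbred lines. A
sequencing-based *reference* platform (GBS-like) discovers and scores
markers in the study population itself: many markers, high missingness,
minimal ascertainment bias. An array-based *candidate* platform
(DArT-like) carries markers pre-selected on a small, independent
discovery panel: fewer markers, little missingness, but the markers are
not a random sample of the population's polymorphisms. Population
genetics estimated from such a panel — allele-frequency spectra,
subpopulation differentiation, kinship — can be distorted, and genomic
selection (GS) accuracy may differ for reasons unrelated to marker
number.

The package asks, for every statistic of interest: *could the candidate
marker set plausibly have been drawn from the reference platform's
markers?* The device is an equal-size **subsampling null**: draw the
candidate's marker count from the imputed reference matrix without
replacement, recompute the statistic, repeat `B` times (1,000 by
default, 100–200 for expensive statistic chains), and locate the
candidate's observed value in that distribution. One-sided,
direction-adaptive empirical p-values are exact multiples of `1/B` and
can be exactly zero when the candidate lies outside the whole null —
the hallmark of ascertainment bias.

## Statistics compared

For the candidate value and each null subsample the pipeline computes:

* the number of subpopulations chosen by BIC over Gaussian mixture
  models fitted to the leading PCA scores (via **mclust**; clustering is
  re-run inside every subsampling replicate, never reused);
* Weir & Cockerham's variance-components Fst over those inferred
  groups, treating inbred lines as haploid draws (residual
  heterozygotes contribute 1/2 to each allele count) and combining loci
  as a ratio of summed components;
* the variance captured by the first principal components;
* the Kullback–Leibler divergence
  `D(N(0, A_ref) || N(0, A_sub)) = (tr(S^-1 R) - n + log det S - log det R)/2`
  between the all-reference relationship matrix and the subset matrix
  (a ridge of `1e-6` times the mean diagonal guarantees
  non-singularity; factorizations, never raw determinants);
* the Pearson correlation of the two relationship matrices'
  off-diagonal upper triangles (the inflated inbred diagonal would
  otherwise dominate);
* the binned minor-allele-frequency spectrum (width 0.05), with 95%
  percentile intervals per bin;
* tag-SNP counts: Carlson-style greedy binning at R-squared thresholds
  0.7/0.8/0.9, tags minimizing missing data — the count of
  non-redundant markers;
* the variance of Euclidean distances between marker score vectors
  (marker clustering in the genome produces near-duplicate score
  vectors and hence an inflated distance variance);
* accuracy as a function of the per-marker missing-rate cap
  (`missing_rate_sweep()`): subsets are selected on raw rates but
  analyzed with their imputed scores, showing that high-missingness
  markers still contribute after imputation (accuracy rises to a
  plateau in the ensemble mean);
* GBLUP cross-validated accuracy per trait, against two nulls
  (equal-size subsamples of all reference markers and of the reference
  tag markers), all sharing one fixed K-fold partition.

### Relationship matrix convention

The realized relationship matrix is computed as `A = X X' / p` with
marker columns centered and `p` the marker count. Centering plus `1/p`
scaling makes matrices built from different marker counts comparable,
which the KL divergence and matrix correlation require; the raw,
uncentered `X X'` is available via `realized_relationship(..., center
= FALSE, scale = FALSE)`. Reported KL values therefore depend on this
convention and are not numerically comparable to analyses that use the
raw product.

### GBLUP

`gblup()` fits `y = 1 mu + g + e`, `g ~ N(0, A sigma2_g)`, by REML: a
single eigendecomposition of `A` reduces the restricted likelihood to
a one-dimensional profile over `delta = sigma2_e/sigma2_g`, maximized
on `log delta` in `[-12, 12]`. GEBVs are the BLUPs of `g`; the
GBLUP/ridge-regression duality (`A = XX'/p`, `lambda =
sigma2_e/sigma2_g`) is asserted in the test suite to `1e-6`. Variance
components are re-estimated inside every training fold, so no
information leaks from validation lines.

Cross-validated accuracy is reported as the **average of per-fold
correlations** between held-out GEBVs and observed line means. We
measured the alternative — pooling all held-out predictions into one
correlation — and found a systematic negative bias of 0.07–0.10 under
a heritability-zero trait in family-structured populations (the global
means couple predictions to out-of-fold phenotypes). Per-fold averaging
is unbiased under the null (|mean| < 0.02 in our checks) and is
therefore the default; `pool = TRUE` restores pooling.

## The synthetic-data generator

All tests run against `simulate_dataset()`, which generates the study
conditions end to end; no external download is needed. The default
configuration (`sim_config()`) is fixed once and describes a desk-scale
version of a winter-wheat breeding program:

* **Population** — 360 F5-derived lines in 12 biparental families of
  30, crossed from 12 recurrent inbred founders. Families are distinct
  founder *pairs*; founders recur across families (half-sib
  connections), and crosses stay within an ancestral pool. Each line
  descends from its F1 by four generations of single-seed selfing with
  Poisson recombination, leaving the expected `(1/2)^4 = 6.25%`
  residual heterozygosity at F1-heterozygous loci.
* **Genome** — 12,000 biallelic loci on 10 chromosomes of 1.5 Morgan.
  Founder haplotypes carry linkage disequilibrium from a
  Gaussian-copula AR(1) along each chromosome (latent correlation
  `exp(-d/0.1)` at distance `d` Morgan), which yields roughly the
  observed ~18% reference-side marker redundancy at R-squared 0.8.
* **Ancestry** — founders descend from two ancestral pools with
  Balding–Nichols differentiation 0.4. Half the loci
  (`shared_ancestry = 0.5`) are *old*: their polymorphism predates the
  pool splits, so their frequencies have drifted apart among pools and
  they also segregate in the discovery panel's gene pool. The other
  half are *young*: variants that arose inside the breeding program,
  shared across pools at one frequency and absent from the panel's
  pool. Old alleles are the pool-stratified, high-differentiation ones;
  this is what lets panel ascertainment inflate Fst (see below).
* **Reference platform** — 4,000 markers sampled uniformly from loci
  with population MAF at or above 0.12 (the analog of a sequencing
  pipeline discarding rare variants as putative errors), then masked
  missing completely at random at 43.9%.
* **Candidate platform** — a 13-line discovery panel is simulated from
  a gene pool at divergence 0.9 from the target (per-locus frequency
  `(1-F) p0 + F u`, `u` an independent draw from the same spectrum,
  defined only for old loci); only panel-polymorphic loci are eligible.
  Marker positions are drawn with weight 25 inside three 0.005-Morgan
  hotspot windows per chromosome, *with replacement*: repeat draws
  model array clones that re-assay the same restriction fragment, and
  produce the ~50% candidate-side redundancy observed for such arrays.
  Cells are masked at 3.1%.
* **Traits** — four traits with line-mean heritabilities 0.29, 0.73,
  0.77 and 0.24, each with 100 additive QTL; noise is scaled so
  `var(e) = var(g)(1-h2)/h2`.

Under these conditions the generator reproduces, by mechanism rather
than by construction, every directional signature the analysis is
meant to detect: candidate excess of rare variants (MAF < 0.2) and
deficit of common ones (MAF > 0.4), higher Fst, higher KL divergence,
lower relationship-matrix correlation, fewer non-redundant markers,
and higher marker distance variance than equal-size reference subsets.

### Why the ascertainment model has this shape

Two standard modeling ideas fail to reproduce the documented bias
pattern, and the failure is instructive. A Balding–Nichols drift of the
panel's frequencies preserves `E[q|p] = p`, and the probability that a
locus is polymorphic in a small panel rises monotonically with its
frequency — so conditioning on panel polymorphism always *favors*
target-common loci and can only produce a rare-variant deficit. And in
any exchangeable single-pool model, per-locus Weir–Cockerham
components are essentially flat in MAF, so no frequency-targeted
sampling moves Fst. The ingredients that work are population-genetic:
frequencies in a long-diverged gene pool are nearly uncorrelated with
frequencies here (the mixture model with large `F`), which makes
target-rare loci ascertainable; and allele age links panel visibility
to differentiation, because only pre-split alleles are polymorphic in
the panel's pool and precisely those alleles have had time to drift
apart among the target's ancestral pools.

### What the generator does not emulate

Missingness is missing-completely-at-random (optionally with
per-marker beta-distributed rates); real sequencing missingness is
coverage-driven and correlated with library and genotype. There is no
sequence-level simulation, no genotyping error, no dominance or
epistasis, no selection during line development, and the candidate
platform's markers are biallelic scores rather than
presence/absence hybridization intensities. Passing tests therefore
demonstrate that the statistics and the subsampling machinery behave
correctly under a realistic neutral model — not that any particular
real dataset will show the same magnitudes.

## Numerical and procedural choices

* **Seeds.** Every stochastic step is deterministic given its seed:
  the generator from `(config, seed)`; imputation per marker from
  `(base_seed, marker_id)` (so results are independent of marker order
  and scheduling); subsampling replicate `b` from `base_seed + b`; the
  CV partition from its own seed and shared across all platforms,
  traits and replicates of a run.
* **Imputation.** Per-marker random-forest classification (100 trees,
  `ceiling(sqrt(p))` predictors per split) trained on the lines
  observed for that marker, with all other same-platform markers as
  predictors, their own gaps pre-filled by the per-marker mode; ties in
  the majority vote break toward the observed major allele. Platforms
  are never pooled. Imputation is single-pass by design — no iterative
  refitting.
* **Known limitation.** Majority-vote imputation has down-biased
  minor-allele recall. At 43.9% missingness this shifts the binned MAF
  spectrum by up to ~0.03–0.08 per bin depending on marker density
  (the candidate platform, at 3.1% missingness, is unaffected in
  practice). Users comparing spectra should prefer the observed-cell
  spectrum (`minor_allele_freq(..., use_observed = TRUE)`) when
  missingness is high.
* **P-values.** `p = r/B`, not `(r+1)/(B+1)`, so exact zeros are
  representable; ties count as extreme; the direction adapts to the
  side of the null median the observed value falls on, with no
  two-sided doubling. A consequence worth knowing: under a true null
  the adaptive p-value reaches `p < 0.05` about 10% of the time (each
  fixed tail is uniform; adapting the direction doubles the rate).
* **Clustering.** Mixtures are fitted on the top 10 PCA score
  dimensions (Gaussian mixtures degenerate when dimensions approach
  the line count), over spherical, diagonal and full covariance
  families with equal and varying volume, `G = 1..10`, initialized by
  mclust's model-based hierarchical agglomeration.
* **Degenerate inputs.** Markers monomorphic among observed calls are
  imputed without a forest; loci monomorphic overall contribute zero
  to both Fst sums; a constant phenotype returns the boundary GBLUP
  fit (`sigma2_g = 0`, all GEBVs zero); clustering failures inside a
  bootstrap replicate mark that replicate's chain statistics missing
  rather than aborting the run.
* **Tag-SNP tie-breaks.** Bin seeds are the markers with most
  above-threshold neighbors (ties: fewest missing cells, then marker
  ID); the bin's tag minimizes missing cells with ties favoring the
  seed. This makes tag counts order-invariant and reproducible;
  alternative traversal orders could shift counts by a few markers.

## Problem sizes used by the checks

The test suite and the acceptance script scale the simulation down so
the full pipeline runs quickly on one core, keeping the study's
*conditions* (missing rates, panel size, divergence, heritabilities)
and shrinking only sizes: most unit tests use 120–200 lines with
300–1,500 markers; the bias-detection checks use 180 lines, 1,500
reference and 500 candidate markers over 20 simulated datasets at
`B = 200`; the acceptance script runs the complete pipeline on the
full 360-line population with 1,200 reference and 500 candidate
markers, `B = 200` for the diversity/redundancy nulls and `B = 50` for
the prediction nulls. The imputation-fidelity checks use a preset
whose marker density per Morgan matches the reference platform's
full-scale density, since local marker density is what governs
imputation quality.
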