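---
title: "Metabolic radiogenomics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic radiogenomics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petromics)
```

## The problem

Tumors are genetically heterogeneous, and a single biopsy samples one site at
one time. FDG PET images the metabolic phenotype of the whole tumor
noninvasively, so quantitative image features — intensity statistics and
spatial texture of the standardized uptake value (SUV) grid — are candidate
surrogate markers for genomic alterations. petromics implements the full
analysis chain needed to test that idea: delineate a tumor volume of interest
(VOI) from PET, extract a fixed catalog of 86 intensity/texture features,
remove scanner batch effects, screen every (feature, gene-alteration) pair
per histology with false-discovery control, cluster patients on their feature
signatures, test the clusters against oncogenic-pathway alterations, and
stratify survival by the resulting groups.

Patient imaging and sequencing data cannot ship with a package, so every
stage is exercised on synthetic inputs with known ground truth: ellipsoidal
lesion phantoms for the imaging stages and a generative cohort model for the
statistical stages. What the tests demonstrate is therefore *methodological
correctness* (the right statistic is computed, planted effects of stated size
are recovered at the expected operating characteristics), not clinical
validity on real cohorts.

## Segmentation

The delineation emulates interactive six-axis gradient segmentation with a
deterministic rule. The volume is smoothed with a Gaussian (sigma = 1 voxel
per axis); rays are cast from the seed along the six signed grid axes; each
ray stops at the most negative directional derivative within the 60 mm search
limit (the metabolic edge). The edge threshold is the mean of the smoothed
intensity midway across the steepest drop of each of the six rays — for a
smoothed sharp boundary this midpoint sits at the half-maximum, which is the
true edge location. The VOI is the 26-connected component of
{smoothed SUV ≥ threshold} containing the seed, clipped to the axis-aligned
ellipsoid spanned by the six detected axis lengths dilated by two voxels.
On sharp noise-free spheres this reproduces the truth mask essentially
exactly (Dice 1.0 at 2 mm spacing); accuracy degrades monotonically with
additive noise, which the test suite checks over a noise ladder. The exact
interior of a proprietary interactive tool cannot be reproduced; the rule
above is the package's own operationalization of six-axis gradient stopping,
and downstream claims rest on the robust feature subset rather than on any
particular delineation.

Metabolic tumor volume (MTV) is voxel count × voxel volume; lesions under
10 cm³ are excluded from texture analysis by `volume_filter()`, because
texture features are unstable on small volumes.

## The 86-feature catalog

`feature_catalog()` defines 86 named features: 55 texture (GLCM 16, GLRM 11,
GLSZM 11, NGLD 9, TFC 3, TFCCM 5) and 31 non-texture (SUV/intensity histogram
25, texture spectrum 2, geometry 4). Conventions that matter:

* **Quantization** — fixed bin *number*: 64 uniform bins over the in-mask
  min–max range, top edge inclusive; a constant VOI maps to a single level.
* **Aggregation** — co-occurrence and run-length matrices are built per
  direction over the 13 unique distance-1 lattice directions, made symmetric,
  normalized, and the features averaged across directions; size zones and
  dependence counts use 26-connectivity/26-neighborhoods. This makes the
  direction-averaged features invariant under the 48 axis-aligned grid
  symmetries (tested).
* **SUVpeak** — mean SUV in the 1 cm³ sphere (radius 6.2 mm) positioned at
  the in-mask voxel maximizing that mean.
* **SUL** — SUV rescaled to lean body mass by the sex-specific James formula;
  reported as missing when sex/weight/height are absent.
* **Histogram entropy** — bits, from the 64-bin in-mask histogram.
* **Texture feature coding (TFC)** — each voxel's 13 opposite-neighbor pairs
  are classified at zero tolerance into flat / slope / extremum / step; the
  voxel code is the sum of classes (13..52, all-flat = 13). TFC features are
  first-order statistics of the code image, the two texture-spectrum features
  summarize the pooled class histogram, and TFCCM features are co-occurrence
  statistics of rank-indexed codes. Codes depend only on the ordering of
  quantized levels, hence are invariant to order-preserving intensity
  rescaling (tested). The coding scheme is the package's documented variant
  of gradient-class texture coding; toolboxes differ in these formulas, so
  the catalog documentation is the normative definition here.
* **Surface area** — coarea estimate: integrate the gradient magnitude of a
  Gaussian-smoothed mask indicator (sigma = 0.8 × min spacing). This is
  accurate for resolved smooth shapes (digital ball within ~1%), while raw
  voxel-face counting overestimates a sphere's area by ~50%. The cost is a
  small underestimate along sharp edges, so a cube's sphericity converges to
  its closed form 0.806 only as the cube grows; masks under 27 voxels fall
  back to exact face counting.

Every matrix-based family is verified against an independent brute-force
enumeration (pair/run/zone/dependence/code counting with naive loops) on
random small VOIs at 1e-10.

**The robust subset.** Downstream stages use 27 of the 86 features that are
comparatively stable across delineation methods. Which 27 is configuration,
not mathematics: the default includes every feature reported in the
published association and cluster-signature tables and is padded with
common, documented choices. Analysts with their own stability study should
pass their list via the `robust` argument.

## Harmonization

Scanner/reconstruction differences shift and scale feature distributions.
`harmonize_features()` applies parametric empirical-Bayes ComBat (via sva):
standardize per feature, estimate per-batch location/scale, shrink toward
normal / inverse-gamma priors across features, remove and back-transform.
Design choices: no biological covariate is protected by default (set
`protect_histology = TRUE` to preserve histology means); harmonization is
applied to all 86 features before robust-subset selection; zero-variance
features pass through with a warning; a single feature is adjusted by direct
location/scale correction since EB pooling needs multiple features. Two
properties are deliberately tested at their *true* tolerances rather than
idealized ones: EB shrinkage leaves a small residual, so a second pass moves
values by under 5% of the shift the first pass removed (not machine zero),
and the grand mean is preserved to ~0.05 SD (not exactly).

## Association screening

Per histology, each gene with ≥ 2 carriers is tested against each robust
feature:

1. **Test routing** — Shapiro–Wilk per group at alpha 0.05; normal values take
   a two-sided Welch t-test (Welch rather than pooled, for unbalanced carrier
   groups); non-normal values are log-transformed (shifted above zero first
   if needed) and re-checked; failing that, the Wilcoxon rank-sum test.
   Groups too small or constant for Shapiro–Wilk route as non-normal.
2. **Effect size** — log2 fold change of group means. When either mean is
   zero the values are first mapped into (0, 1] by
   ((x / max(x)) · (N − 1) + 0.5) / N, applied jointly to both groups with
   the cohort-level maximum and subject count N (the formula leaves the
   within-cohort ordering intact; fixed points 0.95 and 0.05 at N = 10).
   Whether max and N should be cohort-level or group-level is ambiguous on
   its face; cohort-level is chosen so both groups share one scale, and is
   flagged here as a convention.
3. **Multiplicity** — Benjamini–Hochberg across all (gene, feature) pairs of
   one histology's screen (the FDR family), significance at FDR < 0.05.

Operating characteristics are verified by simulation: null p-values uniform,
planted d = 1.5 effects (20 carriers vs 100 non-carriers, 20 planted pairs
among 27 × 100) recovered with ≥ 80% power and ≤ 10% false pairs, and
near-zero discoveries under carrier-label permutation.

## Consensus clustering and PAC

Patients are clustered per histology on z-scored features with consensus
clustering: each of `resamples` iterations draws 80% of patients *and 80% of
features*, clusters them hierarchically (average linkage by default;
complete and Ward available) with Pearson-correlation distance, and the
consensus matrix accumulates co-cluster/co-sample ratios. The cluster number
K minimizes the proportion of ambiguous clustering (PAC): the fraction of
off-diagonal consensus entries strictly inside (0.1, 0.9).

Feature subsampling deserves a note, because it is load-bearing. With
patient subsampling alone, the K = 2 merge of three equidistant true
clusters is decided by the one realized noise pattern of the dataset; every
resample repeats the same merge, the consensus matrix is crisp, and
PAC(2) = 0 ties PAC(3) = 0 — the well-known PAC degeneracy toward small K.
Resampling features redraws that tie-breaking noise per iteration, so an
ambiguous merge shows up as intermediate consensus values and
PAC(2) ≈ 0.68 ≫ PAC(3) = 0 on planted three-cluster data. Determinism is
retained: a fixed seed reproduces the full result.

Representative features are selected in two stages mirroring standard
practice: an omnibus test routed by per-cluster normality and Levene
homogeneity (ANOVA / Welch's ANOVA / Kruskal–Wallis), then all pairwise
t-tests; a feature is representative when the omnibus test is significant
and it misses at most `fallback_misses` pairwise tests (0 by default; 1
admits a feature significant in five of six tests, the documented fallback
for cohorts where no feature passes all tests). No multiplicity correction
is applied inside stage 2 — the all-tests selection rule is itself the
filter.

Cluster-versus-pathway association uses Fisher's exact test on the K × 2
table (seeded Monte Carlo p-value when exact enumeration is infeasible);
pathways altered in none or all patients are degenerate with p = 1.
Reclassification cuts the between-cluster dendrogram (average linkage on
1 − mean between-cluster consensus) into super-groups, so clusters that
split off together from high branches share a label.

## Genomics

Variant calls arrive pre-classified into the four categories MUT (missense),
LoF (frameshift indel, stop-gain), CNV, and FUSION, or with a free-text
detail that is mapped onto them; multiple calls of one category in a
gene/patient collapse to a single flag. A patient carries a pathway
alteration if *any* member gene is altered, per category and overall. The
ten canonical pathway names ship with the package; gene membership is a
required input for real analyses (a synthetic round-robin map serves the
tests), since curated pathway gene lists are maintained outside this
package. `major_gene_filter()` keeps genes altered in more than 3 patients.
`cohort_filter()` does the exclusion-funnel bookkeeping and, when a declared
final cohort size disagrees with the computed remainder, reports the
discrepancy instead of forcing agreement.

## Survival

Kaplan–Meier estimation, log-rank tests and Cox proportional-hazards
regression delegate to the survival package; ties use Breslow's
approximation; censoring is administrative at last follow-up. Covariates
without variation are errors; diverging coefficients (suspected separation)
are flagged in the output rather than silently reported.

## The synthetic generators

`make_lesion_phantom()` builds ellipsoidal lesions: sharp indicator,
optional Gaussian edge blur, intratumoral texture from a smoothed Gaussian
random field (default correlation length 8 mm), additive Gaussian noise,
SUV clipped at zero. The default grid spacing 3.9 × 3.9 × 3.3 mm matches a
common whole-body PET reconstruction, and the default lesion sizes and
SUV levels bracket a typical advanced lung-cancer series (SUVmax roughly
6–18, MTV well above the 10 cm³ filter). Ground truth is exact: the mask is
the set of voxel centers inside the ellipsoid.

`make_cohort()` generates the tabular stages directly: feature =
cluster-block mean + planted gene effect (Cohen's d, since noise is unit
SD) + batch offset/scale + N(0, 1). Cluster mean profiles are mutually
orthogonal feature blocks — a canonical equidistant planted-partition
design. Alterations are i.i.d. Bernoulli at the background rate except for
planted genes (optionally with exact carrier counts); survival is
exponential with cluster-dependent hazards and uniform administrative
censoring. Defaults encode a realistic mixed series: 61/31/45
ADC/SQCC/SCLC patients, two scanner batches at 30/70 with a +0.4 SD /
×1.15 shift on the second, 5% background alteration rate, hazards
0.02/0.04/0.08 events per month. Each patient draws from a seed-derived
sub-stream, so enlarging a cohort never perturbs earlier patients
(tested by hash comparison).

What the generator does **not** emulate: PET physics (scatter, partial
volume, reconstruction artifacts), correlated feature noise, panel-specific
gene frequencies, non-exponential hazards. Passing tests therefore certify
the statistics, not robustness to those real-data complications.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately modest
sizes chosen as the smallest that give the checked statistics stable
operating characteristics: association recovery at n = 120 with 2,700
pairs; harmonization at 60 patients per batch; clustering at n = 60 with
250 resamples (the consensus matrix changes by < 0.05 between 500 and
1,000 resamples on fixed data, so 250 is ample for planted structure);
Cox coverage over 100 simulations of n = 200. Oracle equivalence uses 100
random VOIs up to 6³ at 1e-10. Ties in `which.min` over the PAC curve
resolve to the smallest K, the conventional conservative choice. Exact-test
p-values are discrete, so null uniformity is checked as super-uniformity.

## Known limitations

* The gradient segmenter is an operationalization, not a reimplementation,
  of any proprietary tool; absolute texture values will differ between
  delineations, which is exactly why a robust subset exists.
* Feature definitions follow the package's documented conventions; they are
  not IBSI-exact, and TFC-family formulas in particular vary across
  toolboxes.
* The default robust-27 list and the synthetic pathway map are
  configuration stand-ins for study-specific inputs.
* ComBat here is cross-sectional and parametric; longitudinal or
  nonparametric variants are out of scope.
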