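---
title: "Finding and characterizing low-disease-prevalence population clusters"
author: "phenoclust authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding and characterizing low-disease-prevalence population clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoclust)
```

## The problem

Diabetes, dyslipidemia and hypertension are interrelated metabolic diseases.
Within a large population cohort, some strata carry a markedly lower
prevalence of all three at once; characterizing those strata phenotypically,
genetically and metabolomically can point at protective biology. `phenoclust`
implements that analysis as a reproducible pipeline over three data layers:

1. a **phenome** — a subjects-by-traits table of routine clinical
   measurements with self-reported disease flags;
2. a **genome** — a subjects-by-SNP allele-dosage matrix with annotations;
3. a **metabolome** — 1D ^1^H-NMR plasma spectra on a common ppm axis.

Because biobank data of this kind are access-restricted, the package ships a
synthetic-cohort generator that reproduces the statistical structure each
stage relies on, so the whole pipeline is testable end to end.

## Phenotype quality control

`filter_outliers()` excludes a subject when **any** trait value falls outside
`[Q1 - 3·IQR, Q3 + 3·IQR]` *or* beyond `mean ± 4·SD`, with the bounds
computed per trait on the input table. Numerical choices that the procedure
itself does not pin down, and that we fixed once:

* Quartiles use the type-7 (linear-interpolation) convention, R's default.
* The two outlier rules are combined with OR — exclusion if either fires.
* A constant trait (zero IQR and zero SD) is skipped with a warning rather
  than treated as an exclusion criterion; missing values never trigger
  exclusion.

`impute_missing()` replaces each missing trait value by the median of its
(10-year age band × sex) stratum, falling back to the overall trait median
when the stratum has fewer than 5 observed values. Median imputation is
robust and keeps the pipeline deterministic; multiple imputation is out of
scope.

`stratified_normalize()` regresses each trait on age and sex (linear model,
sex as a two-level factor coded {1, 2}) and scales the residuals to zero
mean and unit SD. Clustering then operates on demographics-adjusted axes in
comparable units. A trait exactly collinear with age/sex has zero residual
variance and is rejected.

`prune_redundant_traits()` removes one member of every highly correlated
trait pair so near-duplicate measurements do not dominate the Euclidean
metric. Pairs with Pearson |r| > 0.6 are walked in descending |r| order; in
each surviving pair the trait with the smaller loading magnitude — the
Euclidean norm of its biplot loadings on PC1–PC2 — is dropped, ties keeping
the earlier column. Whether the threshold applies to |r| or signed r, and
which PCs contribute loadings, are configurable (`use_abs_corr`,
`loading_pcs`); |r| and PC1–PC2 are the defaults because a strongly
*negatively* correlated pair is just as redundant for k-means, and two
components are what a biplot shows. The greedy order can in principle leave
a pair above the threshold when each member anchored the removal of the
other's partner; the report lists every removal with both loadings so this
is auditable.

The stages are tagged (`raw → filtered → imputed → normalized → pruned`) and
refuse to run out of order.

## Clustering

`run_pca()` is exact SVD PCA with a deterministic sign convention (each
loading column's largest-magnitude entry is positive). `kmeans_fit()` wraps
Lloyd's algorithm (`stats::kmeans`, Euclidean distance, uniform-random
initial centers, 300 iterations max, 10 restarts keeping the lowest
within-cluster sum of squares). An initialization that collapses to an empty
cluster is retried with a derived seed rather than patched point-by-point.

`select_k_silhouette()` picks k by the average silhouette
`s(i) = (b(i) − a(i)) / max(a(i), b(i))`; ties return the smallest k. The
silhouette needs all pairwise distances, which is O(n²) memory at biobank
scale, so it is evaluated on a random subsample capped at 5,000 subjects
(shared across candidate k so the comparison is paired).

`assess_stability_jaccard()` re-runs the clustering many times from new
random centers (the reference analysis used 1,000 repeats; tests scale this
to 100) and greedily matches each repeat's clusters to the reference
partition by maximal Jaccard index `J(A,B) = |A∩B| / |A∪B|`, largest first.
Two averaging conventions are reported side by side — the per-reference-
cluster mean and the pooled mean over all (cluster, repeat) pairs — since
either could be meant by a "mean Jaccard index". Each repeat is a full
multi-start fit by default: with a single random start, Lloyd's algorithm
lands in split-blob local optima often enough that the index would measure
optimizer noise rather than the stability of the partition in the data
(`nstart = 1` restores the stricter reading).

Cluster numbering is arbitrary, so the healthy stratum is identified
programmatically: `find_low_prevalence_cluster()` takes the cluster that
minimizes the mean prevalence across the three diseases.
`summarize_clusters()` reports per-cluster trait means (SD) in original
units, disease counts with prevalence percentages (one decimal), and an
optional within-cluster diseased-vs-control comparison by Welch's two-sided
t-test.

## GWAS stage

The association stage is self-contained and desk-scale; it replaces an
external PLINK run while keeping its quality-control semantics:

* **Sample QC** (`qc_samples()`): drop subjects with call rate < 0.95 or
  heterozygosity rate (fraction of non-missing dosages equal to 1) more than
  5 SD from the sample mean; a zero heterozygosity SD disables that filter
  with a log message.
* **SNP QC** (`qc_snps()`): drop SNPs with call rate < 0.95, minor allele
  frequency < 5%, or Hardy–Weinberg exact p < 1e-5. The minor allele is
  recomputed after sample QC; a frequency tie at 0.5 keeps the input allele
  order.
* **HWE** (`hwe_exact_test()`): the exact conditional test — the p-value
  sums the probabilities of all heterozygote counts (at the observed allele
  counts) no more probable than the observed one. The exact test is the
  norm in genotyping QC; a chi-square variant is easy to compute from the
  same counts but is anticonservative for rare alleles.
* **Association** (`logistic_assoc()`): per SNP, logistic regression of the
  outcome on allele dosage (additive coding, 0/1/2) plus covariates, fitted
  by IRLS to relative tolerance 1e-8 (max 50 iterations); two-sided Wald p
  on the dosage term. Subjects missing that SNP are dropped per SNP and
  `n_used` recorded. Constant dosages and separated/non-converged fits are
  flagged (`status`), with missing estimates — never silently removed.
  Genotype principal components (from the centered, MAF-scaled,
  mean-imputed dosage matrix; 8 by default when requested) can be added to
  absorb population structure; they are an internal approximation of the
  usual external PCA.
* **Diagnostics**: `genomic_inflation()` computes
  λ = median(χ²₁ quantiles of 1−p)/0.4549; `significance_report()` flags the
  genome-wide (5e-8) and relaxed (5e-6) tiers and emits a Manhattan-ready
  table. Both thresholds are arguments.

## MWAS stage

Spectra enter after Fourier transform and phasing (FID processing is out of
scope). Preprocessing:

* `remove_water_region()` deletes the residual-water band, 4–5 ppm.
* `airpls_baseline()` estimates a smooth baseline per spectrum by adaptive
  iteratively reweighted penalized least squares: minimize
  `Σ wᵢ(yᵢ−zᵢ)² + λ·Σ(Δ²z)²`, re-estimating weights each iteration so
  points above the baseline (peaks) get weight zero and points below pull it
  down with exponentially increasing force; iteration stops when the
  negative residual mass falls below 0.1% of total intensity or after 15
  iterations. λ defaults to 1e5 (intensity²·points⁴ units; larger is
  stiffer); at very large λ the baseline tends to the straight-line fit of
  the non-peak points.
* `align_spectra()` performs rigid cross-correlation registration: each
  spectrum is shifted an integer number of grid points (≤ 0.02 ppm) to
  maximize correlation with the reference (pointwise median spectrum by
  default), ties preferring the smallest shift, edges padded with the edge
  value. This replaces wavelet-based peak alignment with a simpler method of
  identical intent; it cannot correct non-rigid (per-peak) shifts.

Association is computed per ppm grid point at full resolution (the
acquisition resolution of real data is instrument-dependent; optional
binning is deliberately left out of the default path):

* `mwas_logistic()`: case status (membership in the low-prevalence cluster)
  ~ intensity + age + sex, with Benjamini–Yekutieli FDR control at 1e-3. BY
  multiplies the Benjamini–Hochberg adjustment by `c(m) = Σ 1/k`, which
  keeps FDR control under the strong dependence of neighbouring spectral
  points. The test count m stays at the full number of points even when
  individual fits fail; failed points carry missing adjusted p and cannot
  enter the significance mask.
* `mwas_linear_allele()`: intensity ~ minor-allele count + age + sex, raw p
  reported with **no** multiplicity adjustment — an exploratory scan meant
  to be read alongside the FDR-controlled cluster scan, mirroring how such
  allele-dosage profiles are compared in practice.

## The synthetic cohort generator

`synthetic_config()` defines the study conditions; `generate_phenotypes()`,
`generate_disease_status()`, `generate_genotypes()` and
`generate_spectra()` realize them deterministically from a seed.

What it emulates:

* **Four phenotype strata** over thirteen clinical traits at published
  cluster-mean separations in original units (triglycerides 64.6 mg/dL in
  the healthy stratum vs 152 mg/dL in the high-risk one, HDL 62.3 vs 46.8
  mg/dL, and so on), with correlated blocks (total/LDL cholesterol r = 0.85,
  systolic/diastolic pressure r = 0.75, lipid–BMI couplings) so redundancy
  pruning has real work to do. Cluster weights default to the published
  cluster sizes (4,405/4,496/4,401/3,490 of 16,792).
* **Within-cluster spread**: per-cluster SDs default to the tabulated values
  scaled by `trait_sd_scale = 0.15`. The tabulated SDs describe contiguous
  Voronoi cells of a k-means partition of one continuous cloud; Gaussian
  components with those full SDs overlap so heavily (closest centroids ~1.5
  combined SD apart) that no clustering method could recover the planted
  labels, and the average silhouette would not even select four clusters.
  The 0.15 scale keeps every published cluster mean exact while placing the
  closest pair of planted centroids roughly ten component SDs apart — the
  separable regime the downstream recovery checks assume.
* **Disease status** from logistic models on standardized traits
  (dyslipidemia driven by TG/LDL/HDL, hypertension by blood pressure and
  BMI, diabetes by fasting glucose/HbA1c/BMI), with intercepts and slopes
  fixed once so prevalence lands in the published pattern: ~1–5% in the
  healthy stratum, ~5–18% in the high-risk one, ordered the same way.
* **One causal variant** with per-cluster minor-allele frequencies
  0.2843/0.2419/0.2715/0.2877 (clusters 1–4) — depleted in the healthy
  stratum — plus any number of cluster-independent null SNPs; monomorphic
  columns are redrawn.
* **Spectra** as sums of Gaussian (optionally Lorentzian; line shapes are a
  modelling choice) peaks at canonical plasma positions, with the
  lipoprotein-methyl (~0.86 ppm), leucine (0.95 ppm) and GlycA (2.04 ppm)
  amplitudes lower in the healthy stratum; a smooth non-negative
  raised-cosine baseline; white noise.

What it deliberately does **not** emulate — and therefore what passing tests
cannot show about real data: linkage disequilibrium and admixture (SNPs are
independent given the cluster; relatedness/ancestry filtering is out of
scope), non-Gaussian trait tails and reporting artifacts in self-reported
disease status, FID-level NMR physics (phase errors, water suppression
artifacts, per-peak non-rigid shifts), and any unpublished normalization
applied to the original data. Tests on this generator validate the
*machinery* — calibration, FDR control, recovery of planted structure — not
the biological conclusions.

Default seed: 20200305.

## Problem sizes and reproducibility

The checked operating characteristics use desk-scale sizes chosen to keep
the full suite fast while leaving the statistical margins wide: cluster
recovery on n = 20,000 subjects with k selected from 2–6 and label recovery
over 10 seeds; stability with 100 repeats; GWAS null calibration on 2,000
subjects × 1,000 SNPs and planted-variant detection on 10,000 subjects ×
101 SNPs; MWAS FDR control over 20 null cohorts of 217 subjects × ~2,000
points; baseline recovery on a known quadratic baseline. All stochastic
steps flow from explicit seeds; `scripts/acceptance.R --seed N --out f.json`
recomputes every headline quantity from scratch.

## Known limitations

* The silhouette subsample (5,000) trades exactness for memory; different
  subsample seeds can flip k when two candidate values are nearly tied.
* Greedy Jaccard matching (like any label matching) is heuristic; a
  Hungarian-style optimal assignment would differ only in contrived ties.
* The internal genotype PCs absorb structure only as well as the SNP panel
  estimates it; with few SNPs residual inflation remains (visible in the
  structured-null test, which uses 1,500 SNPs for that reason).
* Welch t-tests in the cluster summary are descriptive, mirroring a cohort
  characterization table; they are not multiplicity-adjusted.
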