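---
title: "Methods: hybrid index, ROH inbreeding and spatial structure in boargen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid index, ROH inbreeding and spatial structure in boargen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`boargen` reimplements, as one coherent and testable toolchain, the
analysis of a continent-scale SNP-array survey of European wild boar:
genotype quality control, estimation of domestic-pig introgression,
quantification of recent inbreeding from runs of homozygosity, and
spatial genetic-structure statistics. This vignette documents the
models, their assumptions, the defaults and the open design choices, in
the package's own terms.

## Data model

Genotypes are diploid biallelic dosages (0/1/2 copies of a counted
allele, `NA` missing) bound to a marker map (chromosome, 1-based bp
position, allele labels) and a sample table (group, sampling location,
coordinates, optional genetic cluster). PED/MAP text files are the
exchange format; since PED does not record which allele to count, the
default orientation counts the lexicographically second observed allele
and a reference-allele table can override it. Every downstream
statistic used here (MAF, Hamming distance, heterozygosity, ROH) is
invariant under orientation flips (d → 2 − d), which the test suite
asserts; orientation only matters when frequencies from two files are
combined, and the pipeline therefore re-reads the pig reference panel
with the wild panel's alleles as reference. BED gene intervals are kept
in their native half-open 0-based convention and converted exactly once,
at the intragenic-exclusion boundary.

## Quality control

The chain runs in a fixed order — locus call rate, sample call rate,
MAF, intragenic exclusion, LD pruning, relatedness — because the source
analysis implies but does not state an order and reproducibility
demands one. Defaults: call rates ≥ 0.95, MAF > 0.025, `indep-pairwise`
windows of 50 SNPs advancing by 5 with r² ceilings of 0.5 (ROH work)
or 0.2 (structure analyses).

LD pruning is greedy within each window: while any retained pair
exceeds the r² ceiling, the member with the lower MAF is dropped (ties:
the later map position). The tie-break is the package's choice — the
procedure is named in the source but its tie handling is not — and is
fixed purely for determinism.

Relatedness uses the method-of-moments IBS→IBD estimator
(the `--genome`-style estimator of the PLINK toolkit): expected
identity-by-state counts given allele frequencies are inverted to
estimates of P(IBD = 0, 1, 2), negative components truncated to zero
and renormalised, and π̂ = P(2) + ½P(1) clamped to [0, 1]. The
estimator runs *separately per sampling location*, with location-level
allele frequencies and MAF > 0.10 filter. This is not a nicety: with
structured populations, panel-wide frequencies let shared local drift
masquerade as relatedness, and on this package's own synthetic panels
that inflation alone can push truly unrelated within-location pairs
toward the 0.183 removal threshold. Individuals participating in the
most pairs at π̂ ≥ 0.183 are removed iteratively (ties: lower call
rate, then id order). The 0.183 threshold is treated as a plain
configuration constant; its provenance is not derivable from first
principles and it is deliberately not given any deeper interpretation.

## The PCoA-projection hybrid index

The estimator opposes two anchor clouds in ordination space: the pig
reference samples, and `n_pure = 20` simulated "pure" wild genotypes
per genetic cluster, drawn per locus as dosage ~ Binomial(2, p̂) from
cluster-level allele frequencies. Hamming distances (allele mismatches:
|dᵢ − dⱼ| summed over pairwise-typed loci, normalised by twice their
number, so opposite homozygotes count 2) are ordinated by classical
PCoA — double-centre −½D², eigendecompose, scale eigenvectors by
√eigenvalue, implemented via `stats::cmdscale` and cross-checked
against `ape::pcoa` in the tests. Each sample's coordinates in the top
`axes_used` axes are projected orthogonally onto the line from the
simulated-pure centroid to the pig centroid and affinely rescaled:
pure → 0, pig → 1.

Three design points were genuinely open and are resolved as follows:

* **Frequency input to the pure simulation.** The construction is
  described in the source analysis as binomial draws with the
  population-level MAF as success probability. Taken literally this
  conflates the minor-allele frequency with the counted-allele
  frequency wherever the counted allele is the major one; `boargen`
  uses the counted-allele frequency of the wild cluster, which equals
  the MAF under the package's default orientation (counted allele =
  wild-minor). Anything else would simulate the wrong genotype
  distribution at roughly half the loci.
* **Number of projection axes.** Unstated in the source; default 2
  (`axes_used`), configurable. Two axes span the pig–wild polar axis
  while damping higher-axis noise; one axis gives nearly identical
  cohort means on synthetic data.
* **Clamping.** Scores are *not* clamped to [0, 1]; classification at
  0.0625 / 0.125 / 0.250 (expected 4th/3rd/2nd-generation backcross
  fractions) is applied to raw scores, preserving information about
  over- and under-shoot.

The estimator has a known small-sample property, visible in the
package's validation experiments: because the pure anchor is simulated
from *estimated* frequencies, sampling noise in p̂ displaces the pure
centroid slightly and biases cohort means upward on the order of +0.01
at a wild pool of 300 (more at smaller pools). The validation
experiment (`benchmark_hybrid_recovery()`) therefore uses a wild pool
of 300 — the scale of the unrelated wild cohort in the motivating
study — 60 pig references, ~5,100 post-filter loci and 50 gene-dropped
offspring per backcross depth; the acceptance script reports the
recovered cohort means and the fitted linearity slope rather than
asserting them here.

Pig-diagnostic alleles are loci whose allele is rare in the wild pool
(< 0.025) but common in pigs (> 0.225), both thresholds on the *same*
allele. The per-sample clustering statistic is the maximum number of
carried diagnostic loci in any 10-Mb sliding window; its permutation
null conditions on the sample's carrier count and permutes *which*
diagnostic loci are carried, so the test is about spatial arrangement
along the genome, not introgression load. The p-value uses the add-one
convention.

## Runs of homozygosity and F_ROH

The detector mirrors the PLINK `--homozyg` semantics: windows of 70
consecutive SNPs with no heterozygotes (and at most 5 missing calls)
vote for each SNP they cover; SNPs whose homozygous-window proportion
reaches 0.05 form candidate runs; runs are split at inter-SNP gaps
above 500 kb, trimmed to homozygous end SNPs, and filtered to ≥ 50
SNPs, ≥ 5 Mb and mean density ≥ 1 SNP/150 kb. The window size, zero-het
rule and segment criteria are the study's stated values; the hit
threshold and missing allowance follow the cited tool's documented
defaults and are exposed in `roh_config()` with that provenance flagged
in the run log. Segment boundaries are the outermost homozygous SNPs
(not window edges), which is what the 5-Mb length filter is applied to.

In the regime `window_max_missing = 0` with a hit threshold below
1/window size, the window scan provably reduces to exhaustive
enumeration of maximal homozygous runs of at least window-size SNPs;
the tests exploit this to check the detector against an independent
brute-force scanner on random instances. At the default threshold of
0.05 the two differ at run edges by design (edge SNPs are covered by
few homozygous windows), which is the trimming behaviour of the
original tool.

F_ROH divides summed segment length by the *scanned* genome — the
union of marker-map stretches on which a qualifying segment is in
principle detectable (`scanned_regions()`), not the assembly length —
mirroring the denominator concept of the source analysis. Classes at
0.125 / 0.0625 / 0.03125 are the pedigree expectations for offspring of
half siblings, full cousins and half cousins.

## Spatial structure

Structure analyses exclude hybrids and inbred individuals
(F_hybrid > 0.0625 or F_ROH > 0.0625) and downsample to at most five
individuals per location (seeded), countering uneven-sampling bias in
ordination. The Mantel statistic correlates off-diagonal upper
triangles; by default it runs at population level (mean between-location
Hamming distance vs. great-circle distance between mean location
coordinates) to reduce autocorrelation, with the individual-level
option available. Significance is a two-sided permutation test with
add-one correction, jointly permuting rows and columns; for tiny
problems all n! permutations can be enumerated exactly. Axis–geography
association uses Spearman rank correlations of per-location mean
ordination scores against longitude and latitude (all four pairs
reported). MLH is heterozygous/typed loci per individual, with
equal-count decile classes for mapping (ties split by sample order);
its linear model is OLS on longitude, F_hybrid and F_ROH with latitude
screened separately, a condition-number guard against collinear
designs, and the F statistic, adjusted R² and residual d.f. reported.

Regional allele selection resolves an internally contradictory rule in
the source ("MAF within the focal region larger than 0.5" cannot hold
if "minor" is defined within-region): `boargen` selects loci whose
*panel-scale minor* allele is *locally major* (frequency > 0.5 within
the focal region), which reproduces the intended "alleles typical for
the focal region". Per-location mean frequencies of the selected
alleles are interpolated by ordinary kriging: coordinates are projected
to kilometres by an equirectangular projection about the mean latitude
(the interpolation model assumes planar coordinates); the empirical
semivariogram (12 bins to half the maximum distance) is fitted by
weighted least squares (weights Nⱼ/hⱼ², multi-started on the range)
over spherical, exponential and gaussian families; the ordinary-kriging
system with Lagrange multiplier is solved per grid node (default 0.5°
spacing over the bounding box with 10% margin). Weights sum to one by
construction and the prediction interpolates exactly at data points
when the nugget is zero — both asserted in tests. Duplicate locations
are averaged first. Note the fitted `range` parameter is
family-specific (practical range for exponential/gaussian, plateau for
spherical), so ranges should only be compared within a family.

## The synthetic-data generator

The generator produces the statistical structure the analysis assumes,
not a forgery of any real dataset:

* **Differentiated populations**: Balding–Nichols — population
  frequency ~ Beta(p(1−F)/F, (1−p)(1−F)/F) around ancestral
  p ~ U(0.05, 0.95) — so Var = F·p(1−p), and two pools drawn at the
  same F have pairwise FST ≈ F. The wild/pig divergence for validation
  work is F = 0.15, consistent with strong wild–domestic
  differentiation on commercial SNP panels.
* **Clines**: per-population logit-scale frequency shifts proportional
  to the standardised projection of the population's coordinates on a
  direction vector; strength 0 is the identity and frequencies stay in
  (0, 1). This creates genuine isolation by distance for the Mantel and
  kriging stages.
* **Pedigrees with truth**: gene dropping under the Haldane model
  (crossover count ~ Poisson(chromosome Morgans), positions uniform, no
  interference) over an 18-autosome, ~2.26-Gb, ~22.6-Morgan pig-like
  genome at 1 cM/Mb. Haplotypes are segment lists of founder-haplotype
  ids, so each simulated individual carries its exact pig-ancestry
  fraction and autozygous tract list as ground truth. Backcross depth g
  has expected ancestry 2⁻ᵍ; half-sib/full-cousin/half-cousin matings
  have expected autozygosity 1/8, 1/16, 1/32, and the tests verify the
  simulated means against an independent path-counting kinship oracle.
* **Markers**: regular spacing, default 1/100 kb, at which the ROH
  criteria (50 SNPs / 5 Mb / 150 kb density) are satisfiable — sparser
  maps make the scanned genome empty by design, not by accident.
* **Missingness**: uniform at a declared rate (default 1% in the
  benchmark suite).

What the generator does *not* emulate: linkage disequilibrium within
populations (loci are independent given frequencies), mutation,
genotyping artefacts (batch effects, allele dropout, beadchip version
differences), non-HWE within populations, and continuous spatial
admixture between named populations. Passing tests therefore
demonstrate correctness of the estimators under their own assumptions
and calibrated behaviour at realistic sizes — not robustness to
array-specific artefacts in real data.

## Problem sizes and numerical choices

The validation experiments use sizes chosen to mirror the study scale
while staying comfortable on a single CPU: hybrid recovery at ~5,100
loci with a wild pool of 300, pig pool of 60 and 50 offspring per
backcross depth; autozygosity at 200 offspring per mating class over
the full 18-autosome genome; ROH oracle equivalence on 100 random
200-SNP instances; Mantel calibration at 500 null replicates of 20
locations with 99 permutations each; the deterministic end-to-end run
on a 2-chromosome benchmark suite. The full test suite runs in about
two minutes.

Numerical conventions worth knowing: distances of exactly zero between
duplicate samples are preserved (PCoA places them coincident);
eigenvalues below 1e−12 are treated as null and negative eigenvalue
mass is reported rather than silently dropped; the kriging system
solves the semivariogram form with γ(0) = 0, so data-point predictions
are exact for any nugget when a node coincides with a datum; permutation
p-values always use the add-one convention and so never return 0;
all stochastic functions take explicit seeds and the pipeline refuses
configurations that omit one.

## Limitations

F_hybrid is a projection proxy, not a likelihood-based admixture
estimate: it is approximately linear in true ancestry under the
validated conditions but inherits a small positive bias from
frequency-estimation noise in the pure anchor, and single-individual
scores scatter around the cohort mean with the variance of backcross
ancestry itself. The ROH detector reproduces a windowed heuristic, not
an HMM-based IBD caller; very short or marker-poor autozygous tracts
are invisible by construction. The moment IBD estimator assumes the
location sample approximates its own source population; with very few
individuals per location its frequency estimates are noisy and π̂
conservative. Kriging assumes second-order stationarity after the
planar projection; strongly anisotropic clines are fitted
isotropically.
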