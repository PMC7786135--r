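---
title: "Metabolic covariance networks from regional FDG-PET uptake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic covariance networks from regional FDG-PET uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A metabolic covariance network is a group-level object. Each subject
contributes one number per brain region — the mean FDG uptake across the
voxels of that region, normalized to a cerebellar reference — and an edge
between two regions measures how strongly their uptake covaries *across
subjects*. There is therefore one network per group, never one per subject,
and the sampling unit for all inference is the subject.

The fitted network object (`covnet`) is the package's central class, with
`print`, `summary`, `plot` and `as.matrix` methods.

`mcnet` implements the full chain:

1. **Regional extraction** (`flip_lr()`, `smooth_gaussian()`,
   `normalize_to_reference()`, `extract_uptake()`): volumes in a common
   space are left–right flipped when the epileptogenic focus is
   right-sided (so all foci are analysed on the left), optionally smoothed
   with an isotropic Gaussian kernel (default FWHM 5 mm), divided by the
   mean value of the cerebellar reference region, and averaged within each
   label of the parcellation. The default node catalogue holds 53 regions:
   39 left neocortical and 6 left subcortical regions (AAL naming) plus 8
   brainstem arousal nuclei (AAN naming).
2. **Network estimation** (`covnet()`): the 53×53 matrix of partial
   correlations between regions, controlling for all remaining regions.
3. **Seed covariance map** (`seed_correlations()`): plain Pearson
   correlations between the insula and each of the other 52 regions, with
   t-based two-sided p-values, a Bonferroni threshold `alpha/52`, and a
   positive-sign filter (negative covariances are never declared
   connections).
4. **Graph analysis** (`threshold_by_density()`, `nodal_metrics()`,
   `global_metrics()`, `metric_curve()`): binary graphs over a
   connection-density grid, summarised by the trapezoidal area under the
   curve (AUC).
5. **Null models** (`maslov_sneppen_rewire()`,
   `normalized_small_world()`): degree-preserving surrogates for the
   small-world coefficients.
6. **Group comparison** (`regional_ttests()`, `permute_network_metric()`,
   `seed_edge_contrast()`).

## Partial correlations with fewer subjects than regions

With 17 subjects and 53 regions the sample covariance matrix is singular,
so "the correlation between two regions controlling for all others" is not
defined through a plain matrix inverse. `covnet()` makes the construction
well-defined by analytic shrinkage: the sample correlation matrix `R` is
replaced by `(1 - lambda) R` off the diagonal (a shrink toward the
identity), variances are restored, the result is inverted, and partial
correlations are read off the precision matrix `Omega` as
`-Omega_ij / sqrt(Omega_ii * Omega_jj)`.

The intensity `lambda` is chosen analytically as the ratio of the summed
estimated variances of the correlation coefficients to their summed
squares, clipped to `[0, 1]` — the standard analytic-shrinkage estimate for
correlation matrices. It is fully data-driven, deterministic, recorded in
the fitted object, and can be overridden (`shrinkage = 0` recovers the
classical regress-out-everything estimate when subjects outnumber regions,
which the tests verify against an independent residual-correlation oracle).
Two consequences worth knowing:

* For independent noise the analytic intensity approaches 1 and the
  network honestly degenerates toward empty — there is nothing to recover.
* The intensity differs between groups (structured data shrink less), which
  is intended: each group's network is the best-regularized estimate of
  *its* covariance.

No p-values are attached to partial correlations; the weighted network is
consumed by density thresholding, and significance machinery is reserved
for the seed analysis where `df = n - 2` is well-defined.

## Thresholding and graph statistics

`threshold_by_density()` zeroes negative weights and keeps the
`k = round(density * n(n-1)/2)` largest remaining weights, binarized.
Ties spanning the cut are resolved by ascending node-index pair, so results
are bit-reproducible. If fewer than `k` strictly positive weights exist,
only those are kept and a warning reports the attained density; zero-weight
edges are never invented.

Definitions used (all on binary graphs):

* clustering `C_i`: triangle density among neighbours, 0 for degree < 2;
* `Cp`: mean `C_i`; `Lp`: mean shortest path over *connected* pairs only
  (keeping the small-world coefficients finite at sparse densities);
* global efficiency: mean of `1/d(i,j)` with disconnected pairs
  contributing 0; local efficiency of a node: global efficiency of its
  neighbour-induced subgraph;
* betweenness: Brandes counting with fractional credit for tied shortest
  paths, summed over unordered pairs;
* hierarchy `beta`: minus the least-squares slope of `log C_i` on
  `log k_i` over nodes with `k_i >= 2` and `C_i > 0` (the scaling
  `C(k) ~ k^(-beta)`); reported as `NA` when fewer than two eligible nodes
  remain or all eligible degrees coincide (e.g. a ring lattice);
* synchronizability: the Laplacian eigenratio `lambda_2 / lambda_max`,
  which is 0 for disconnected graphs and 1 for a complete graph.

The hierarchy and synchronizability formulas are the standard
definitions from the graph-theoretic neuroimaging literature, stated here
explicitly because conventions vary between toolboxes.

Every metric curve is evaluated over the density grid 5–50% in 5% steps
(10 points) by default and summarised by the trapezoidal AUC on the actual
density abscissa, so irregular grids integrate correctly.

## Null models

`maslov_sneppen_rewire()` performs double edge swaps — replace `(a,b)`,
`(c,d)` by `(a,d)`, `(c,b)` when all four nodes are distinct and neither
replacement exists — preserving every node's degree, hence density and node
count. Defaults: 10 successful swaps per edge, an attempt budget of 100 per
edge (rigid graphs are returned unchanged with the attained swap count
recorded), and 100 surrogates per ensemble. `gamma = Cp / <Cp_null>`,
`lambda = Lp / <Lp_null>`, `sigma = gamma / lambda`. The swap loop is
implemented in C++ using R's RNG, so a single seed reproduces the whole
ensemble.

## Group inference

The two group networks are single objects, so a two-sample test on "the"
network metric has no within-group sampling distribution to draw on.
`permute_network_metric()` therefore relabels subjects into groups of the
original sizes, refits both networks and recomputes the metric-AUC
difference; the two-sided p-value is `(1 + #{|null| >= |obs|}) /
(n_perm + 1)` (1000 permutations by default). When the requested
permutation count reaches the number of distinct relabelings, all of them
are enumerated and the p-value is exact. A paired t-test across
per-density values (`curve_ttest()`) is available as a descriptive
summary only — densities are nested, not independent.

Regional uptake is compared by Welch's t-test (group sizes and variances
differ) with Holm step-down correction, restricted by the pipeline to the
regions showing significant insula covariance in the epileptic-like group.

## The synthetic generator and what it does (not) emulate

`simulate_uptake()` draws regional uptake vectors from a multivariate
Gaussian parameterized directly by its precision matrix: the diagonal is
`1/base_variance` and each coupling edge with partial correlation `rho`
sets the off-diagonal to `-rho sqrt(Omega_ii Omega_jj)`. Positive
definiteness is validated, never repaired silently, and a build/read-back
round trip of the partial correlations is exact to numerical precision.
Group sizes default to 17 and 14 subjects.

One standardization step sits between the precision matrix and the
sampler: the implied covariance is rescaled so that every region's marginal
variance equals `base_variance` (default SD 0.1 on reference-normalized
uptake). Partial and marginal correlations are invariant to this diagonal
rescaling, but without it couplings near the positive-definiteness
boundary inflate marginal variances by an order of magnitude, producing
unphysiological uptake values and drowning the mean shifts that model
hypometabolism. With the default scale, the -0.15 shift on coupled regions
is a 1.5-SD effect — comfortably detectable at the default group sizes.

The epileptic-like condition (`epileptic_coupling()`) couples the insula
through two pathways: a four-region *relay* of its anatomical neighbours
(Rolandic operculum, superior temporal gyrus, Heschl's gyrus, thalamus)
with strong seed partials (0.40) and weak mutual partials (0.06), and a
broad 20-region *community* (the opercular/temporal/parietal/occipital,
subcortical and raphe regions of the insular covariance pattern) with
weak per-pair partials (0.07 to the seed, 0.024 mutual). All coupled
regions are hypometabolic by 0.15 normalized-uptake units (1.5
inter-subject SDs at the default variance scale).

The split is forced by two pieces of mathematics, both visible in pilot
simulations of the generator. First, a positive-definite precision matrix
caps uniform partial correlations in a k-region block at roughly `1/k`,
so a broad community can never carry strong per-edge partial structure.
Second, the marginal collinearity that strong broad covariance implies
inflates the sampling variance of estimated partial correlations and
attenuates them under shrinkage: in near-singular configurations a true
partial of 0.3 estimates at about 0.07 while pure-noise pairs reach 0.2,
so "strong" edges inside a collinear block never rank above the noise
when the network is thresholded. A concentrated, low-collinearity relay
escapes this attenuation (its edges rank in the top few percent of
weights), while the weak community cumulatively raises the *marginal*
insula correlations into the range where seed edges survive Bonferroni
correction at `n = 17`. The control-like condition is fully uncoupled.
Parameters were fixed by pilot simulation of the generator itself,
against pre-stated design goals, and then frozen.

The phantom generator renders regions as axis-aligned voxel blocks with a
mirror-symmetric left/right layout (midline blocks span the full
left-right axis), which is sufficient to test flipping, smoothing,
normalization and extraction exactly. It does not emulate PET physics: no
point-spread function, no partial-volume effects, no anatomical shapes.
Consequently, passing tests demonstrate the correctness of the
computational chain, not robustness to scanner noise or registration
error.

## Numerical choices

* Smoothing uses a separable truncated Gaussian (4 sigma) with boundary
  renormalization, so constant volumes are exact fixed points and interior
  mass is conserved; `sigma = FWHM / (2 sqrt(2 ln 2))` per axis in voxels.
* Flipping operates on the first voxel axis and requires the image to be
  in a left-right-first orientation; unknown orientation is an error.
  Flipping precedes smoothing, which precedes intensity normalization.
* All RNG consumers take an explicit seed and restore the caller's RNG
  state; pipeline stage seeds derive deterministically from the single
  configuration seed, so `run_pipeline()` is byte-reproducible.
* Degenerate inputs fail with classed errors naming the offending region
  or edges (constant columns, empty reference regions, non-PD couplings,
  undersized phantom grids).

## Problem sizes used by the test-suite

The statistical checks run at sizes chosen to keep the suite quick while
leaving comfortable margins: partial-correlation recovery at n = 5000
subjects on 6 regions; seed-map calibration over 2000 simulated null
datasets of 17 subjects; permutation type-I calibration over 200 dataset
pairs with 199 relabelings on a 4-density grid; the qualitative two-group
pattern over 11 replicate pairs with 30-member null ensembles. The
package defaults (10 densities, 100 nulls, 1000 permutations) are used by
the end-to-end determinism check and the acceptance script.

## Limitations

* MRI co-registration, DARTEL-style spatial normalization, tissue
  segmentation and partial-volume correction are out of scope; volumes
  must arrive in a common space.
* Whether the original study regularized its partial correlations — and
  how it attached p-values to differences between two group-level networks
  — is not documented; the shrinkage estimator and the subject-relabeling
  permutation test are this package's explicit, defensible replacements,
  not reconstructions.
* Graph analysis is binary; weighted variants, modularity and rich-club
  statistics are not implemented.
* The synthetic generator produces Gaussian data with a block coupling
  structure; real FDG-PET covariance has spatial autocorrelation,
  site/scanner effects and non-Gaussian tails that it does not attempt to
  model.
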