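---
title: "Methods: perfusion-diffusion deficit mapping and MD-restricted connectivity statistics"
author: "tbiconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perfusion-diffusion deficit mapping and MD-restricted connectivity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and assumptions

`tbiconn` analyses co-registered, preprocessed multimodal MRI from a
three-group rodent TBI design — sham, injured + vehicle, injured + treated —
imaged at post-injury days 1 and 7. Everything upstream of co-registered
images is out of scope: template construction, nonlinear registration, DWI
denoising/eddy correction and rsfMRI motion/slice-timing correction are
assumed done by external tools. Consequently the package *refuses*
mismatched inputs (different dims or space tags) instead of resampling:
silent resampling would hide registration failures that the upstream tools
are responsible for.

## The measurement model, stage by stage

**Relative CBF.** Perfusion is acquired as a single coronal slice. Because
contralateral perfusion renormalises within hours in this injury model, the
contralateral cortical grey matter is a valid within-subject reference:
every voxel is divided by the mean CBF over parcels with
`hemisphere == "contra"`, `tissue == "cortex"` intersected with the slice.
A deficit voxel has rCBF strictly below 0.5; a voxel at exactly 0.5 is not
a deficit (the defining phrase is "less than 50 %"). The operation is
scale-invariant, so arbitrary scanner units are acceptable.

**MD z-maps.** Sham volumes define voxelwise mean and SD maps
((n−1)-denominator); a subject's z-map is `(MD − μ)/σ`, and low-MD tissue
is `z < −1.7`, one-sided — acutely *reduced* MD (cell swelling / reduced
extracellular space) is the phenomenon of interest, and elevated MD is
deliberately not masked. Voxels with zero or undefined sham SD are excluded
from the analysis domain with a count; the threshold corresponds to a
nominal voxelwise false-positive rate of Φ(−1.7) ≈ 4.5 %.

Which sham timepoint anchors day-7 z-maps is not fixed by the design; the
pipeline defaults to the matched sham day-7 session (`sham_reference =
"match"`) and can reuse day 1 (`"d1"`) when a matched session is missing.

**Tensor fit (optional stage).** When raw DWI signals are supplied, the
tensor is fitted per voxel by unweighted least squares on the log signal.
The estimator used by the original processing chain is not specified
anywhere we could anchor to, and at the noiseless-to-moderate noise levels
of the synthetic data the log-linear fit is exact to numerical precision
(the acceptance suite demands 1e-6 relative recovery of MD and FA).
Negative eigenvalues are clamped to zero before FA with a per-voxel flag;
voxels with fewer than 7 usable measurements (the parameter count) are
masked rather than fitted.

**Congruence.** The per-subject statistic is the fraction of
perfusion-deficit voxels that are also low-MD, counted inside the CBF slice
footprint ∩ ipsilateral hemisphere. It deliberately *conditions on the CBF
mask* (share of low-perfusion tissue that is also low-MD). With no
CBF-deficit voxel the ratio is 0/0; it is reported as 1.0 with a warning so
that lesion-free (sham-like) subjects do not read as discordant. The domain
is a parameter because the original report is ambiguous about whether
cortical voxels only were counted.

**Functional connectivity.** Parcel series are band-passed 0.01–0.2 Hz with
a frequency-domain (FFT) filter: multiplication in the frequency domain is
exactly zero-phase, so no temporal shifts are introduced across parcels.
Pearson correlations are Fisher-z transformed with r clipped to
±(1 − 1e−12) so degenerate perfectly-correlated pairs stay finite (and are
flagged). Negative correlations are retained in the matrix; their handling
is deferred to thresholding and two-tailed testing.

**Edge sets.** A parcel is *low-MD* at the group level when ≥ 10 % of its
voxels are low-MD in ≥ half of the injured subjects — both cutoffs are
exposed configuration keys, because no published rule exists. An edge is a
low-MD edge when at least one endpoint is a low-MD parcel (`rule = "any"`,
the default; `"both"` is available). The any-endpoint rule maximises
sensitivity to connections *from* damaged regions, which matches the
reported finding pattern (ipsilateral-to-contralateral effects). Low-MD and
normal-MD sets always partition the full edge list.

**Graph metrics.** After proportional thresholding — keep the top
`ceiling(sparsity × E)` positive-z edges, ties broken by (z, lexicographic
pair) so results are platform-reproducible — graphs are *binary*. Binary
metrics admit exact brute-force oracles (exhaustively verified on every
4-node graph and on random graphs to n = 12), which weighted variants would
not; and sparsity thresholding is inherently binarising. The nodal
clustering coefficient and local efficiency are summed over the 8-level
grid 10–45 % in 5 % steps, so each nodal sum lies in [0, 8]. Negative-z
edges are excluded before ranking: sign-mixed rankings are undefined in the
source design, and positive-weight proportional thresholding is the
dominant convention.

One documentation note: a "complete graph at every sparsity level" is
impossible under the ceiling rule for any graph with more than a handful of
nodes (10 % of edges can never be all edges), so the upper bound of the
nodal sums is attained only in degenerate cases; the suite instead verifies
the sums against independent level-by-level recomputation.

**Inference.** Group contrasts on Fisher z (cross-sectional) or subject
Δz = z(d7) − z(d1) (temporal, a difference-in-differences) use two-tailed
permutation tests with one shared subject permutation per iteration across
all edges — preserving the between-edge dependence — and
`p = (1 + #{|T*| ≥ |T|}) / (n_perm + 1)`. Small designs are enumerated
exactly. The apnea covariate (injury-severity proxy, undefined for shams)
is removed by Freedman–Lane-style residualisation; crucially the contrast
weights are also projected onto the residual space (`a = (I − H)w`), since
permuting plain residuals against unprojected weights is conservative
exactly when the covariate correlates with group — the situation the
covariate exists for. Sham-involving contrasts omit the covariate. FDR is
Benjamini–Hochberg per contrast per edge set at q < 0.01 (strict), applied
across edges; "regions" in the source description is ambiguous between
edges and nodes, and edges are used, configurably.

## The synthetic cohort generator: what it states, what it emulates

The generator is the package's stated world: sham n = 10, injured vehicle
n = 10, injured treated n = 8; 450 frames at TR = 2 s; apnea mean 8.1 s over
5–14 s, coupled to per-subject lesion severity; an ipsilateral ellipsoidal
lesion (~310 voxels by default) where CBF is multiplied by 0.4 at day 1
(against the 0.5 deficit criterion) and largely resolves (×0.85) by day 7.

*MD model.* Sham MD is a smooth low-order spatial field (so sham SD maps
are estimated on structure, not on a constant) plus i.i.d. Gaussian voxel
noise; the MD deficit is `md_z_depth` sham SDs deep, default **4.0**. That
default is an a-priori detection-error calculation, not a tuned value: at
depth 3 the voxel miss rate is Φ(1.7 − 3) ≈ 0.10, which alone biases
measured congruence to ~0.65 — outside the ±0.05 recovery band the
acceptance criteria specify — while at depth 4 the bias is below 0.01.

*Congruence dial.* A configurable fraction (`md_fraction`, default 0.70) of
lesion voxels carries the MD deficit, sampled separately inside and outside
the CBF slice so the slice-domain ground-truth congruence equals the dial
up to rounding. The `true_congruence` recorded in the ground truth is
computed by exhaustive counting with the same `overlap_fraction` logic the
pipeline uses, and the two agree exactly by construction (tested).

*Bilateral MD.* By default the MD-deficit voxels are mirrored into the
homotopic contralateral position (`bilateral_md = TRUE`). Acute MD
reduction in this injury model is spatially diffuse and bilateral, and the
reported connectivity effects — including contralateral hyperconnectivity —
all fall inside low-MD territory. With a strictly unilateral MD deficit and
the any-endpoint edge rule, contralateral-contralateral effects could never
be low-MD edges, making the stated effect structure unrepresentable.

*Connectivity model.* Time series are multivariate normal draws from
block-structured correlation targets: baseline 0.1 everywhere, homotopic
pairs 0.6; injury subtracts 0.3 from homotopic coupling of lesioned parcels
and adds 0.15 between the lesion's contralateral mirrors and the rest of
the contralateral hemisphere; treatment adds back 0.2 on the depressed
homotopic edges at day 7. Every block target is Cholesky-checked at
configuration time and a non-positive-definite combination is rejected
naming the offending group/timepoint block. Effect sizes are chosen so that
at 450 frames (Fisher-z standard error ≈ 0.047) the injected effects are
unambiguous at the permutation floor while null edges stay null.

*Persistence.* At day 7 the MD deficit reverts to baseline
(pseudo-normalisation) except in a persisting subset: 15 % of deficit
voxels for vehicle, 80 % for treated — the treatment *prevents*
pseudo-normalisation, which is the counter-intuitive trajectory the design
probes. Ground truth records the per-group persisting masks.

*What the generator does not emulate* — and what a green test therefore
does not establish: spatially autocorrelated physiological noise (the
smooth-field + i.i.d. choice is a stand-in; real MD noise correlation
lengths are unknown), scanner drift and motion residuals, haemodynamic
autocorrelation in the time series (frames are i.i.d., so Fisher-z
variances are optimistic relative to real rsfMRI), partial-volume effects
at lesion borders, and sex as a covariate.

## Numerical and design choices

* Voxel indices are 0-based on disk (NIfTI convention) and 1-based in R;
  masks are written as unsigned 8-bit NIfTI, labels as int32.
* NIfTI-1 I/O is implemented in the package because the deployment
  environment provides no R NIfTI reader; the subset (single-file, five
  datatypes, diagonal sform, descrip-carried space tag) is round-trip exact
  and was cross-validated against an independent Python implementation.
* Permutation p-values are never 0 by construction; FDR significance is
  strict (`q < α`).
* The permutation stream is seeded per contrast and restored afterwards, so
  pipeline runs are byte-identical for a fixed seed (tested).
* The exact-enumeration path activates automatically when the number of
  group assignments is ≤ 20 000.
* Degenerate inputs: all-zero DWI voxels are masked, not fatal; constant
  parcel columns are dropped with a warning before correlation; a constant
  covariate is dropped with a warning; fewer positive edges than a sparsity
  level requests keeps all positive edges and records the shortfall.

## Known limitations

* Single-slice CBF means congruence is a slice statistic, not volumetric.
* Binary graph metrics only; weighted variants are out of scope.
* The low-MD parcel classification thresholds (10 % of voxels, half the
  injured subjects) are package choices exposed as parameters, not
  published values.
* The MD-metric correlation pools subject × region pairs; alternative
  poolings (e.g. group-mean regional values) would give different r.
* Freedman–Lane residualisation assumes a linear nuisance effect of apnea
  on Fisher z.
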