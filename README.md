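# tbiconn

Multimodal MRI analysis for experimental traumatic brain injury (TBI) in
rodents: perfusion-deficit mapping, mean-diffusivity (MD) lesion mapping,
perfusion-diffusion congruence, and resting-state functional-connectivity
(FC) statistics restricted to metabolically compromised tissue — with a
synthetic multimodal cohort generator that provides full ground truth for
every stage.

## Who this is for

Groups analysing co-registered small-animal MRI after experimental injury
(e.g. lateral fluid percussion), with three kinds of input per subject:

* a single coronal arterial-spin-labelling CBF slice,
* a 3D diffusion-derived MD volume per timepoint (or raw multi-direction
  DWI signals plus a b-table for the built-in tensor fit),
* parcel-averaged resting-state fMRI time series (or 4D frames plus an
  integer parcellation).

All images must already be in one common space; the package enforces this
contract and never resamples.

## The analysis model

**Perfusion.** Each CBF slice is normalised by the mean CBF of contralateral
cortical grey matter, giving relative CBF (rCBF); a perfusion deficit is a
voxel with rCBF < 0.5 (strictly).

**Diffusion.** MD is referenced voxelwise against sham mean/SD maps:
`z_v = (MD_v − μ_v) / σ_v`; low-MD tissue is `z < −1.7`. The diffusion
tensor, when fitted here, uses unweighted log-linear least squares with
MD = tr(D)/3 and FA the normalised eigenvalue variance.

**Congruence.** Per subject, the fraction of perfusion-deficit voxels that
are also low-MD, within the CBF slice ∩ ipsilateral hemisphere:
`|CBF∧MD∧dom| / |CBF∧dom|` (an empty denominator reads 1.0, with a warning).

**Connectivity.** Parcel series are zero-phase band-passed (0.01–0.2 Hz),
correlated (Pearson) and Fisher-z transformed. Edges are partitioned into a
*low-MD* set (≥ 1 endpoint in a low-MD region) and a *normal-MD* set.

**Graph metrics.** FC matrices are proportionally thresholded over the
sparsity grid 10–45 % in 5 % steps (positive edges only, deterministic
tie-break); the binary clustering coefficient `C_i = 2t_i / k_i(k_i−1)` and
nodal local efficiency (global efficiency of the neighbour subgraph) are
summed across the grid per node.

**Inference.** Two-tailed permutation tests (default n = 5000) on group
differences of Fisher z (or of Δz between timepoints), with apnea duration
at impact as a nuisance covariate handled by Freedman–Lane-style residual
permutation, and Benjamini–Hochberg FDR at q < 0.01 per edge set.

## Worked example

```r
library(tbiconn)
cfg <- run_config(simulate = list(seed = 42), n_perm = 5000, seed = 42)
report <- run_pipeline(cfg, "runs/demo")
report$group_mean_congruence
#> [1] 0.678
sapply(report$contrast_summary, function(s) s$n_significant)
#>   injured_vs_sham_d1_low_md injured_vs_sham_d1_normal_md
#>                          40                            0
#>    treated_vs_vehicle_delta        treated_vs_vehicle_d7
#>                           5                            5
#>   injury_vehicle_vs_sham_d7    injury_treated_vs_sham_d7
#>                          40                           39
report$md_metric_correlation$cc[c("r", "p")]
#> $r [1] -0.2601   $p [1] 2e-04
aggregate(persistent_low_md_mm3 ~ group, report$subjects, mean)
#>            group persistent_low_md_mm3
#> 1 injury_treated              5.453125
#> 2 injury_vehicle              1.782812
#> 3           sham              0.081250
```

Reading the output: injured animals show a mean perfusion–diffusion
congruence of 0.68 (the generator's target is 0.70); every FDR-significant
injury effect falls in the low-MD edge set and none in the normal-MD set;
the treated group shows FC potentiation on the depressed homotopic edges
(5 significant Δ edges, all hyper); and treated animals retain ~3× the
persistent low-MD tissue volume of vehicle (pseudo-normalisation
suppressed), each group contrast significant by permutation test.

The MD–metric correlations are negative (low MD with higher summed
clustering/efficiency), reflecting the generator's contralateral
hyperconnectivity inside low-MD mirror regions.

## Command line

```sh
tbipipe=$(Rscript -e 'cat(system.file("cli/tbipipe", package = "tbiconn"))')
Rscript "$tbipipe" simulate  --config cfg.json --out cohort/ --seed 7
Rscript "$tbipipe" run       --config run.json --out runs/r1 --seed 7
Rscript "$tbipipe" perfusion --cbf cbf_d1.nii --labels labels.nii --parcels parcels.tsv --slice-y 16 --out perf/
Rscript "$tbipipe" zmap      --md md_d1.nii --sham-dir shams/ --out zmap/
Rscript "$tbipipe" fc        --ts ts_d1.tsv --tr 2 --out fc/
Rscript "$tbipipe" graph     --fc fc/fc.tsv --out graph/
```

## Layout

* `R/` — modules: synthetic cohort generator, NIfTI/TSV/JSON I/O,
  perfusion, diffusion, congruence, connectivity, graph metrics,
  permutation statistics, pipeline orchestration, CLI.
* `vignettes/tbiconn-methods.Rmd` — the methods vignette: model,
  parameters, generator design, numerical choices, limitations.
* `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles.
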