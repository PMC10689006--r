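Package: tbiconn
Title: Perfusion-Diffusion Deficit Mapping and Functional Connectivity
    Analysis for Experimental Traumatic Brain Injury
Version: 0.1.0
Authors@R:
    person("TBI", "Imaging Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for multimodal small-animal MRI analysis after
    experimental traumatic brain injury: relative cerebral blood flow
    (rCBF) mapping and perfusion-deficit masks, sham-referenced mean
    diffusivity (MD) z-score lesion maps, perfusion-diffusion congruence,
    parcel-level resting-state functional connectivity (Fisher-z Pearson
    matrices), binary graph metrics summed over a proportional-sparsity
    grid, and covariate-adjusted permutation inference with
    Benjamini-Hochberg false discovery rate control. Includes a
    synthetic multimodal cohort generator with fully known ground truth
    for validating every stage, minimal NIfTI-1 image input/output, and
    a command-line entry point orchestrating the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
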