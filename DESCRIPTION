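Package: lesionometry
Title: Tract-Based Lesionometry of White Matter Hyperintensities from
    Diffusion MRI
Version: 0.1.0
Authors@R:
    person("VCAP", "Imaging Tools", email = "imaging@example.org",
           role = c("aut", "cre"))
Description: Subject-specific lesionometry of white matter hyperintensities
    (WMH) from multi-shell diffusion MRI. Decomposes the diffusion signal
    into three tissue signal fractions (intracellular anisotropic,
    intracellular isotropic, extracellular isotropic) by single-shell
    3-tissue constrained spherical deconvolution, generates whole-volume
    probabilistic streamline tractograms on the white-matter fiber
    orientation distribution with length filtering and SIFT-style pruning,
    builds per-subject lesionometry regions of interest from streamlines
    traversing WMH voxels, and relates ROI microstructure and lesion load
    to age-adjusted epigenetic age (AgeAccelGrim) cross-sectionally and
    longitudinally. Includes a synthetic phantom and two-timepoint cohort
    generator with planted effect structure so the full pipeline is
    testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
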