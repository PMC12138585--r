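Package: stopnet
Title: Lifespan Trajectories of Iron, Myelin and Diffusion Metrics in the
    Stopping Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies age-related change in the cortico-subcortical
    stopping network (inferior frontal gyrus, presupplementary motor area,
    subthalamic nucleus and their connecting tracts). Computes voxelwise
    iron and myelin concentration maps from quantitative MRI contrasts
    (R1, R2*, QSM), generalised fractional anisotropy from fibre
    orientation distribution amplitude samples and multi-shell apparent
    diffusion coefficients, aggregates them over region and tract masks,
    selects polynomial lifespan trajectories by BIC with Cook's-distance
    influence pruning, and runs mediation and age-partialled correlation
    analyses. Includes a fully synthetic cohort generator with phantom
    volumes whose regional values invert the biophysical and diffusion
    models, so the entire pipeline is testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
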