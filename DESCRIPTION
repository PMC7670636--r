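Package: pvstwin
Title: Perivascular Space Segmentation and Twin Heritability of Regional
    dPVS Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated segmentation of MRI-visible dilated perivascular
    spaces (dPVS) on 3D T2-weighted-like volumes via multiscale Hessian
    vesselness filtering with patch-based 3D convolutional-network
    false-positive refinement, followed by classical-twin variance-component
    analysis of the resulting regional volumes: univariate ACE/AE/CE/E
    maximum-likelihood models and bivariate Cholesky ACE models yielding
    narrow-sense heritability, genetic correlation and shared heritability
    with profile-likelihood confidence intervals. Includes a synthetic-data
    module generating tubular phantoms with ground truth, test-retest noise
    realizations, and ACE-simulated twin cohorts, so every stage can be run
    and validated without restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
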