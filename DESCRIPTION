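Package: rfmritools
Title: Resting-State fMRI Metrics, Multi-Site Harmonization and
    Replicability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for voxel-wise intrinsic brain
    function studies in multi-site cohorts with a two-by-two
    diagnosis-by-sex design.  Provides a synthetic-cohort generator with
    known ground truth (site batch effects, homotopic/local/spectral signal
    structure, motion, sex-differential brain-behavior coupling), motion
    quality control with framewise displacement, nuisance regression
    (24-parameter motion model, CompCor, polynomial trends, optional global
    signal), band-pass filtering and Gaussian smoothing, five voxel-wise
    resting-state metrics (seed-based intrinsic functional connectivity,
    voxel-mirrored homotopic connectivity, regional homogeneity via
    Kendall's coefficient of concordance, degree centrality and fractional
    amplitude of low-frequency fluctuations), empirical-Bayes ComBat site
    harmonization, voxel-wise group general linear models with Gaussian
    random field cluster-level correction and a Freedman-Lane permutation
    oracle, partial eta-squared effect sizes with noncentral-F confidence
    intervals, an effect-size-based robustness/replicability classifier,
    leave-one-site-out stability, and sex-by-symptom-severity interaction
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    sva,
    car
Config/testthat/edition: 3
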