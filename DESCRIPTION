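Package: kneedea
Title: Tibiofemoral Contact Stress from Radiograph-Registered Bone Models by Discrete Element Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiautomated estimation of tibiofemoral contact stress for
    population-scale knee studies. Bone surfaces derived from MRI are aligned
    to weight-bearing radiographs by 3D-to-2D silhouette registration: a
    virtual radiographic scene is reconstructed, model silhouettes are
    ray-cast onto the film plane, and a covariance matrix adaptation
    evolution strategy (CMA-ES) minimises a symmetric distance-transform cost
    against traced bone edges. Contact stress is then computed by discrete
    element analysis (DEA): rigid bones coupled through a compressive-only
    Winkler spring bed representing the combined cartilage layer, iterated to
    vertical load equilibrium. Reliability of derived peak and mean
    compartment stresses is quantified with Shrout-Fleiss ICC(2,1) and
    Bland-Altman agreement summaries. A synthetic knee phantom generator
    supplies ground-truth geometry, rendered edge images, segmentation-like
    perturbations and ratings tables for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
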