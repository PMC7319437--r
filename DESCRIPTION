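Package: schicr
Title: Single-Cell Hi-C Contact Matrix Analysis and Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stores thousands of per-cell Hi-C contact matrices in a single
    scool (single-resolution cooler) HDF5 container and takes them through
    quality control, normalization, matrix balancing (iterative correction
    and Knight-Ruiz), bin merging, dimension reduction (raw, PCA, k-nearest
    neighbors, MinHash locality-sensitive hashing, short-versus-long-range
    contact ratios, A/B compartment tracks), k-means and spectral
    clustering, per-cluster consensus matrices and contact-decay cluster
    profiles. Includes a seeded synthetic single-cell Hi-C generator with
    known cluster structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    rhdf5,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    mclust,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
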