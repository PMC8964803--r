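Package: ptycg
Title: Maximum-Likelihood Ptychographic Reconstruction with a Partitioned
    Conjugate-Gradient Solver
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and reconstructing 2-D ptychography data.
    Implements the far-field ptychography forward operator (probe-times-patch
    extraction followed by an orthonormal Fourier transform per scan position)
    and its exact adjoint, the Poisson maximum-likelihood cost and Wirtinger
    gradient, and a Dai-Yuan nonlinear conjugate-gradient solver with
    backtracking line search. A partitioned solver decomposes the object into
    strips with halo-duplicated diffraction patterns and runs each iteration
    in four stages (local gradient, gather-scatter direction, all-reduce line
    search, update with border exchange) over pluggable logical-worker
    backends, reproducing the monolithic solver's iterates. Includes a
    synthetic-data generator (Siemens-star and procedural-texture objects,
    disk and Gaussian probes, jittered raster scans, optional Poisson noise),
    SSIM/PSNR/convergence metrics with global-phase alignment, an HDF5
    dataset container, image export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rhdf5,
    jsonlite,
    yaml,
    tiff,
    png,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
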