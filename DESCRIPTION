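Package: tomoslice
Title: Parallel-Beam Tomographic Reconstruction and Pre-Processing for
    Synchrotron Slice Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A CPU-only toolkit for two-dimensional (slice-based)
    parallel-beam tomography as practised at synchrotron beamlines:
    flat/dark-field normalization, zinger (outlier) correction,
    wavelet-Fourier ring-artifact suppression, Paganin single-step phase
    retrieval and entropy-based rotation-center estimation; matched
    forward/back-projection operators with selectable discretization
    kernels and an explicit sparse-matrix view; analytic (filtered
    backprojection, Fourier-gridding "gridrec") and iterative (SIRT,
    CGLS, ML-EM/OSEM) slice reconstruction behind a single dispatch
    interface; a plugin registry for user-supplied algorithms with a
    reference FISTA total-variation solver; a synthetic phantom and
    raw-count simulator including limited-angle scan scenarios; and
    data-exchange-style HDF5 plus 32-bit float TIFF input/output with a
    small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    rhdf5,
    stats,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
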