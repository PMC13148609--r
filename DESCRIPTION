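Package: ctpipe
Title: Synchrotron Micro-CT Processing: Raw Correction, Phase Retrieval
    and Tomographic Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A CPU reference implementation of a synchrotron micro-CT
    beamline processing pipeline. Covers the three canonical stages:
    raw correction (dark/flat-field normalisation, bad-pixel repair,
    threshold median filtering, trimming, tile stitching by dead
    reckoning or phase correlation), pre-processing (single-distance
    TIE-Hom phase retrieval, polynomial beam-hardening correction) and
    tomographic reconstruction (automatic centre-of-rotation estimation
    by Fourier phase correlation, sinogram ring-artefact correction by
    stripe sorting and large-stripe removal, filtered back-projection
    and FDK with a registry of reconstruction filters, circle masking,
    limited-angle support and memory-bounded streaming slab output).
    Ships a synthetic acquisition simulator (analytic ellipse phantoms,
    forward projection, detector artefact and noise models) that writes
    the same HDF5 acquisition dialect as the readers, so the whole
    pipeline is testable without external data, plus a command-line
    interface for simulation, processing and scan planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    tiff,
    RNifti,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
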