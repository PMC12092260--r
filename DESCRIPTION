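Package: fpscan
Title: Planar Fabry-Perot Photoacoustic Tomography: Simulation, Reconstruction and Vascular Quantitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for a planar Fabry-Perot (FP) sensor
    photoacoustic tomography scanner. Models the FP interferometer transfer
    function, bias-wavelength optimization and noise-equivalent-pressure
    statistics; generates multibeam scan patterns, acquisition timing,
    subsampling masks and sliding-window frame schedules; synthesizes
    vessel-tree and layered-skin initial-pressure phantoms and planar sensor
    time series via an exact Fourier-domain forward operator with a matched
    numerical adjoint; reconstructs initial pressure by one-step k-space
    backprojection or by iterative total-variation regularized least squares
    with a non-negativity constraint for subsampled (compressed-sensing)
    acquisitions; provides 2D elevational receive beamforming for video-rate
    line-scan imaging; and quantifies images by contrast-to-noise ratio,
    skeleton-based vessel density, suprathreshold voxel counts, tortuosity
    index and ROI time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
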