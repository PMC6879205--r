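Package: ribbonq
Title: Quantification of Hair-Cell Ribbon Synapses and Calcium Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for quantifying ribbon synapses and
    fluorescence signals in zebrafish lateral-line hair cells. Segments
    presynaptic ribbon (Ribeye) and postsynaptic density (MAGUK) puncta
    from multi-channel 3D stacks (rolling-ball background subtraction,
    difference-of-Gaussians band-pass, normalized thresholding, seeded 3D
    watershed, minimum-size filtering), pairs ribbons with postsynaptic
    densities by 3D centroid distance against a radius-sum threshold,
    measures channel intensities inside ribbon ROIs, analyses evoked and
    spontaneous calcium traces (dF/F0, percentile baselines, bleach
    correction, event detection, two-channel Pearson correlation,
    mock-normalized baselines), and fits four-parameter logistic
    dose-response curves. A synthetic phantom generator with full ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
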