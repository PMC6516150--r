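Package: vasomech
Title: Passive Arterial Mechanics and Vascular Wall Remodeling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of passive arterial stiffness and wall
    remodeling from ex vivo myography, in vivo imaging and histology.
    Implements wire-myography diameter-tension regression with
    Laplace-based estimation of the physiological diameter, pressure
    myography mechanics (wall geometry, incremental distensibility,
    circumferential stress-strain and the exponential stiffness exponent
    beta with the incremental elastic modulus), aortic lumen-area kinetics
    from ECG-gated cine MRI, transit-time pulse wave velocity, an elastin
    rectilinearity toolbox (median/rolling-ball preprocessing,
    segmentation, skeletonization, branch decomposition and chord-to-arc
    ratio), stained-section quantification (trichrome area fractions,
    morphometry, polarized picrosirius color classes, immunofluorescence
    intensity with maximum-entropy thresholding, second-harmonic texture
    moments, nuclei counts), and the accompanying statistical layer
    (Grubbs outlier exclusion, group comparisons, Sidak adjustment).
    Seeded synthetic-data generators emulate every input with known
    ground truth so each stage supports parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-image.R'
    'synthetic.R'
    'wire.R'
    'pressure.R'
    'hemodynamics.R'
    'elastin.R'
    'histo.R'
    'stats.R'
    'io.R'
    'pipeline.R'
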