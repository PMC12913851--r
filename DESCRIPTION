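Package: chromodyn
Title: Quantifying DNA-Damage Localization and Chromatin Remodeling from
    Two-Channel Live-Cell Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Time-resolved analysis of laser micro-irradiation experiments
    imaged by confocal time-lapse microscopy with a DNA counterstain.
    Computes mask-restricted image cross-correlation spectroscopy (ICCS)
    colocalization fractions between a DNA-damage marker channel and the
    counterstain channel, DNA density at damage foci, region mean
    intensities and coefficient of variation, and fits one-phase
    association (recruitment) and decay (relaxation) kinetics. Includes a
    ground-truthed synthetic time-lapse generator with Poisson photon
    statistics so the whole pipeline can be exercised and validated
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
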