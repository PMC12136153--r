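Package: specsens
Title: Photoreceptor Spectral Sensitivity and Inter-Photoreceptor
    Inhibition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for sharp-electrode intracellular recordings
    from insect photoreceptors. Converts time-voltage traces into response
    features (baseline statistics, amplitude, polarity, onset latency,
    half-maximum duration), transforms isoquantal spectral responses into
    spectral sensitivity curves by Naka-Rushton inversion of V-log(I)
    series, estimates the wavelength of peak sensitivity by fitting a
    rhodopsin absorbance template, classifies cells into spectral classes
    and detects delayed hyperpolarizing (color-opponent) inhibition, and
    compares inhibition proportions across groups of animals with binomial
    standard errors and logit-link mixed models with a random intercept
    per individual. Includes a synthetic-recording generator with known
    ground truth for validating every stage, and a quantum-catch style
    model of predicted photoreceptor excitation by wing reflectance
    spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    lme4,
    lmerTest,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
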