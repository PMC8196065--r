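Package: dropletcondense
Title: Condensation Statistics and Kinetic Modelling of DNA Nanotube
    Assembly in Microemulsion Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the self-assembly of DNA (and DNA-RNA
    hybrid) nanotubes inside water-in-oil microemulsion droplets from
    fluorescence time-lapse microscopy. Provides a seeded synthetic image
    generator for droplet populations with ground-truth annotations, a
    circular-Hough droplet detector with per-droplet interior pixel
    extraction, per-droplet skewness and excess-kurtosis "condensation"
    statistics (including a unique-binned-value variant) aggregated into
    population timecourses, and a deterministic ODE model of RNA-triggered
    tile activation, nucleation-elongation polymerization, transcription
    under decaying polymerase activity, and RNase H mediated tile
    deactivation, with pulse metrics and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tools,
    deSolve,
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    withr,
    e1071,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
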