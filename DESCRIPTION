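Package: bubblometry
Title: Quantification of X-Ray-Induced Bubble Formation in Wet-Embedded Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tomography-free gas volumetry and bubble-growth kinetics from
    phase-contrast cineradiograph sequences of wet-embedded soft tissue.
    Provides flat-field and tissue-context correction of radiograph stacks,
    Beer-Lambert inversion of excess optical depth into gas volume, bubble
    segmentation and overlap tracking with circularity-based classification of
    geometrically constrained growth (free, vessel-confined, alveolar-stepped),
    windowed power-law fits of cumulative bubble volume after onset,
    micro-gas-chromatogram peak integration with onset-aligned relative
    concentration summaries, cumulative-dose accumulation and adiabatic
    heating bounds, and a synthetic radiograph/chromatogram phantom with
    exported ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    pracma,
    rlang,
    stats,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
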