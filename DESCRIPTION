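Package: spherequant
Title: Quantification of Immunofluorescence in Neurosphere Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An image-quantification pipeline for multichannel fluorescence
    micrographs of enteric neurosphere cultures. Segments neurosphere regions
    on a pan-neuronal marker channel, isolates nuclei on the DAPI channel with
    distance-transform watershed splitting, gates particles by area and
    circularity, classifies per-nucleus marker positivity by thresholded mean
    intensity, integrates counts and proportions per neurosphere, measures
    migration and neurite-extension distances from spheroid borders, and
    applies the group-comparison statistics (Kruskal-Wallis or one-way ANOVA
    with Dunn's or Tukey's post hoc tests and Holm adjustment). Includes a
    synthetic multichannel image generator with known ground truth so that
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
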