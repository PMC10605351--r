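Package: chromagrain
Title: Quantification of Chromatin Marks and Cohesin Granularity in
    Fluorescence Images of Cell Nuclei
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for quantifying euchromatin (H3K4me3),
    heterochromatin (H3K9me3) and cohesin signals in multichannel 2D
    confocal images of cell nuclei. Segments nuclei from a DNA
    counterstain, eliminates extranuclear background, computes
    per-nucleus size and per-channel signal amounts, detects label
    granules by an adaptive bimodal-histogram threshold with
    median-filter refinement and a minimum-size rule, and compares
    experimental groups with two-sample t or Kruskal-Wallis tests and
    tiered significance annotation. Includes a synthetic-scene
    generator with planted ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
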