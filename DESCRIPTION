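Package: fretbench
Title: Simulation and Quantification of FRET-Based ERK Activity Imaging in Zebrafish Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify Forster resonance energy transfer (FRET) readouts of
    ERK kinase activity in zebrafish embryos expressing an intramolecular
    CFP/YPet biosensor, together with a synthetic-microscopy phantom generator
    that provides ground truth for every stage. Implements band-window and
    non-negative least-squares spectral separation of lambda stacks,
    ratiometric FRET indexing of regions of interest, acceptor-photobleaching
    FRET efficiency and donor-acceptor distance estimation, embryo morphometry
    (axis ratio, body length), immunoblot and immunofluorescence densitometry,
    and the group statistics used for genotype and dose-response comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tiff,
    jsonlite,
    pracma,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
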