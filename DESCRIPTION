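Package: conmapr
Title: Contact Map Visualization with Diagonal Annotation Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parse, compare and draw protein residue-residue contact maps and
    binned distance predictions (distograms) together with per-residue sequence
    annotations. Reads CASP RR files (contact and RMODE 2 binned-distance
    dialects), PSIPRED ss2 secondary structure, IUPred disorder, TOPCONS
    membrane topology, ConSurf conservation grades, FASTA sequences and a
    simple custom-track instruction format. Extracts Cbeta contact maps from
    PDB coordinate models, superposes predicted and model-derived maps into a
    matched / model-only / predicted-only classification, and scores the
    satisfaction of long-range contact predictions as a model-quality proxy.
    Figures place up to nine annotation tracks in the empty band along the map
    diagonal (slots -4 to +4, with optional mirroring), support half-map
    composition of two maps over one sequence, and a heatmap mode for
    distograms; output is deterministic SVG or PNG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
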