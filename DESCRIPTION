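Package: dotscreen
Title: Quantification and Interaction-Preference Calling for
    Proximity-Biotinylation Dot-Blot Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pairwise proximity-biotinylation
    interaction screens read out on high-density dot-blot membranes.
    Fits the dot lattice on two-channel membrane images (streptavidin
    biotinylation signal and anti-H3 loading control), extracts
    background-corrected per-dot intensities, normalizes by the loading
    control, aggregates replicates with quality-control exclusion rules,
    and classifies each prey protein as preferring one of two bait
    translocons by a twofold-change rule.  Includes a synthetic screen
    generator with planted ground truth for validation, and downstream
    Kyte-Doolittle hydropathy profiling of signal peptides, including
    N-terminal prefix-swap variants and signal-peptide-only reporter
    constructs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
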