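Package: methanoredox
Title: Metabolic and Bioenergetic Reconstruction of Nitrate-Dependent
    Anaerobic Methane Oxidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to turn an annotated archaeal (meta)genome and
    transcriptome into a metabolic and bioenergetic model of
    nitrate-dependent anaerobic methane oxidation (AOM). Provides
    coverage/GC contig binning, a proteome-wide census of heme-c
    attachment motifs (CxxCH and variants) to identify multiheme
    c-type cytochromes, threshold-based homolog calling from tabular
    pairwise-alignment hits, RPKM transcript quantification, and a
    redox-thermodynamics engine (delta G = -nF delta E) with an
    electron ledger for reverse methanogenesis and proton-motive-force
    bookkeeping. Seeded synthetic-data generators with ground-truth
    manifests make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
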