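Package: dfgout
Title: Chimeric Template Ensembles for Kinase DFG-out Homology Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric classification of protein kinase catalytic-domain
    conformations (DFG motif, activation loop, glycine-rich P-loop and
    alphaC-helix) in the common PKACalpha (PDB 1ATP) reference numbering,
    and combinatorial construction of 18 chimeric template structures per
    kinase: a DFG-in acceptor C-lobe fused with one of six N-lobe donors
    (P-loop x alphaC classes) and one of three activation-loop donors,
    together with target-to-template alignments in PIR and aligned-FASTA
    formats, ready for any downstream comparative-modelling engine. Includes
    a synthetic scaffold generator that poses every classifier observable
    exactly, so the full pipeline is testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
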