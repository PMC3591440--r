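Package: frdsig
Title: Signature Motifs and Conservation Profiles for the Ferric Reductase Domain Superfamily
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Sequence-signature analysis for the ferric reductase domain (FRD)
    superfamily (NADPH oxidases, ferric reductases, YedZ/STEAP). Computes
    per-column conservation profiles and information content from clade
    alignments, maps homolog positions onto the human NOX2 reference via
    pairwise global alignment, classifies sequences into clades from
    signature residues at reference positions (heme-coordinating histidines,
    the His-119/Thr-178/Gly-179 oxidase motif, the YedZ/STEAP arginine
    replacement), detects EF-hand loops and domain architectures, discovers
    discriminating positions between clade profiles, and generates seeded
    synthetic clade-structured families with planted signatures for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    seqinr,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
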