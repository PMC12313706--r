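Package: plastocub
Title: Comparative Plastome Structure, Codon Usage Bias, and Selection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated plastid (chloroplast)
    genomes: detection of the quadripartite LSC/IRb/SSC/IRa architecture and
    inverted-repeat junction geometry; per-gene codon-usage-bias statistics
    (positional GC content, RSCU, Wright's effective number of codons) with the
    ENC-GC3s, Parity Rule 2, and neutrality-plot diagnostics; sliding-window
    nucleotide diversity over multiple-genome alignments; and pairwise Ka/Ks
    estimation by the Nei-Gojobori counting method with Jukes-Cantor correction.
    Includes a synthetic plastome generator with planted inverted repeats,
    controllable codon usage, and per-gene selection strength, so every analysis
    stage can be exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
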