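Package: afpconverge
Title: Convergence Diagnostics for Alanine-Rich Type I Antifreeze Protein Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess whether the alanine-rich alpha-helical (type I)
    antifreeze proteins of distantly related fishes are homologous or arose by
    convergent evolution. Implements windowed k-of-n dot-matrix comparison of
    cDNAs with sense and antisense matching, synonymous codon-usage profiling
    centred on the four Ala codons, annotation of the helical ice-binding
    features shared by these peptides (11-residue Thr periodicity, i/i+4 salt
    bridges, helix caps, internal helix breakers), alternative-reading-frame
    analysis of trinucleotide codon runs that could seed poly-Ala coding
    sequence, and a synthetic gene-family simulator so the whole pipeline can
    be exercised and validated without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
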