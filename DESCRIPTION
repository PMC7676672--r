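Package: cpSCUB
Title: Synonymous Codon Usage Bias Analysis of Chloroplast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of synonymous codon usage bias (SCUB) in annotated
    chloroplast (plastid) genomes. Reads GenBank flat files, extracts
    protein-coding gene models with exon/intron structure, computes RSCU,
    CAI and third-position codon-usage frequencies over the 59 synonymous
    codons, resolves codon usage by intron number and exon position with
    explicit split-codon assignment, derives CpG-context proxy ratios for
    methylation-mediated C-to-T conversion, and ordinates species by
    hierarchical clustering and principal component analysis. Includes a
    synthetic annotated-plastome generator with known ground truth so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
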