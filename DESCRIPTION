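Package: cricketcub
Title: Codon Usage Bias Analysis for Transcriptome Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide codon usage bias analysis for sets of in-frame coding
    sequences, as applied to de novo insect transcriptomes. Implements CDS
    quality filtering, nucleotide and dinucleotide composition by codon
    position, relative synonymous codon usage (RSCU), Wright's effective
    number of codons (ENC) with the mutation-pressure expected-ENC curve and
    deviation ratios, principal component analysis of the RSCU matrix,
    detection of expression-correlated preferred codons restricted to
    GC-conservative synonymous codon pairs, and comparison of gene subsets
    (e.g. chemosensory families) against the genome background. Includes a
    synthetic CDS generator with mutation-only and translational-selection
    regimes so every stage is testable with known ground truth.
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
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
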