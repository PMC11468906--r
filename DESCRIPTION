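Package: neovax
Title: Neoantigen Prioritization and Tandem-Minigene mRNA Vaccine Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for designing tandem-minigene mRNA cancer vaccines from
    somatic variant calls: applies transcript-coordinate variants to coding
    sequences and extracts mutant/wild-type 27-mer peptide windows, scores and
    ranks candidate neoantigens by a configurable multi-feature composite
    (peptide-MHC affinity, agretopicity, expression, variant allele
    frequencies, binding stability, immunogenicity), assembles the full
    vaccine mRNA (signal peptide, glycine-serine linkers, MHC class I
    trafficking signal, untranslated regions, polyA tail) with a
    coordinate-annotated region map, chooses codons by a joint minimum
    free-energy / codon-adaptation-index lattice dynamic program over a
    Nussinov pair-score model, and provides the closed-form arithmetic for
    lipopolyplex formulation, ELISpot responder calling, and tumor-burden
    summaries. A seeded synthetic-cohort generator makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    optparse
Config/testthat/edition: 3
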