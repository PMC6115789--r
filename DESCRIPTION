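Package: mirtarp
Title: Interspecies miRNA Target Prediction by Seed Matching and
    Hybridization Thermodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts microRNA target sites across species boundaries
    (host miRNAs on viral genomes and viral miRNAs on host transcripts)
    using a two-stage pipeline: an exact k-mer scan for runs of at least
    b consecutive Watson-Crick complementary bases (default 7), followed
    by a nearest-neighbor thermodynamic assessment of the intermolecular
    miRNA-target hybrid duplex with a minimum-free-energy cutoff
    (default -25 kcal/mol). Local secondary-structure accessibility of
    each candidate site is reported via Zuker-style minimum-free-energy
    folding of the surrounding target window. Includes a synthetic
    fixture generator with planted sites, a dinucleotide-preserving
    shuffle for negative controls, TSV/GFF3 reporting, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    IRanges,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
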