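Package: hgtmatch
Title: Alignment-Free Detection and Quantification of Horizontal Gene
    Transfer from Long Exact Sequence Matches
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects horizontal gene transfer (HGT) between distant taxa
    from long maximal exact matches (MEMs) shared by their genomes. Builds
    normalised match-length distributions (MLDs) for pairs and sets of
    taxon groups, fits the predicted r^-3 power-law tail with a fixed slope
    to estimate an effective transfer rate (the prefactor A), and dates
    individual transfer events from match length and mutation rate. A
    forward simulator fragments transferred segments by Poisson mutations,
    reproduces the steady-state power law, and generates FASTA genome
    pairs with planted xenologous segments for end-to-end validation.
    Weighted functional-enrichment arithmetic (hit totals, standard errors,
    control-set sampling) is included for downstream gene-category
    analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, Sequencing, Alignment, ComparativeGenomics, Software
RoxygenNote: 7.3.3
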