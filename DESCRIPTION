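Package: cpPhylogeo
Title: Chloroplast DNA Phylogeography: Haplotype Networks, Nested Clade
    Analysis, Gene Flow and Skyline Demography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for intraspecific phylogeography from a
    single non-recombining, maternally inherited locus such as a chloroplast
    DNA spacer. Collapses aligned sequences to haplotypes, computes Nei
    haplotype and nucleotide diversity, builds minimum spanning networks
    with all co-minimal connections, performs nested clade analysis with
    clade and nested-clade distances, permutation tests and an editable
    inference key, estimates pairwise Hudson FST and island-model gene flow
    (Nm), tests isolation by distance by Mantel permutation, reconstructs
    neighbor-joining trees with Kimura two-parameter distances and bootstrap
    support, and derives classic and generalized skyline plots of effective
    population size from ultrametric genealogies. A structured-coalescent
    island-model simulator with finite-sites mutation generates realistic
    test data for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    geosphere,
    vegan,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
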