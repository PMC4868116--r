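Package: treekit
Title: Phylogenetic Tree Comparison, Taxonomy Queries and Evolutionary
    Model Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A command-line-friendly toolkit for phylogenomics: newick tree
    parsing and manipulation, duplication-aware tree comparison
    (Robinson-Foulds distance, branch congruence, TreeKO speciation distance
    via duplication-free decomposition of gene trees), local queries against
    NCBI taxdump-format taxonomy databases with tree annotation,
    likelihood-ratio tests between nested codon substitution models with a
    selective-pressure classification scheme, and supermatrix alignment
    concatenation with partition tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    jsonlite
Config/testthat/edition: 3
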