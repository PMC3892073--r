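Package: ChemRegistry
Title: Structure-Searchable Chemical Compound Registration Database
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An embeddable chemical compound registration database with
    chemical structure search. Stores multi-component compounds (mixtures),
    batches and bar-coded containers on top of a unique, immutable structure
    table keyed by standard InChIKey. Searches combine exact, substructure,
    SMARTS, similarity (Tanimoto/Tversky/substructure-Euclidean) and gross
    formula modes with property filters, molecular weight ranges, paging with
    cached total counts, mixture-aware distinct semantics and a
    screening-versus-filter query planner. Includes SD-file import/export,
    optional role-based read filtering, a deterministic synthetic fixture
    generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rcpp,
    ChemmineOB,
    yaml,
    tools,
    utils,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'conditions.R'
    'fingerprint.R'
    'store.R'
    'security.R'
    'match.R'
    'registry.R'
    'sdf.R'
    'fixtures.R'
    'parse.R'
    'props.R'
    'search.R'
    'weights.R'
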