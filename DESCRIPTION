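Package: concavebind
Title: Interface Convexity and Concave-Scaffold Binder Design Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Shape analysis and library-design computations for de novo
    protein binders built on concave five-helix scaffolds. Computes
    solvent-accessible surface area by deterministic Shrake-Rupley
    sampling, defines protein-protein interfaces from apo/holo dSASA,
    fits spherical surfaces to interfacial atoms by RANSAC to obtain a
    signed convexity (reciprocal sphere radius, negative for concave
    patches), screens five-helix bundles against geometric admission
    rules, turns site-saturation mutagenesis deep-sequencing counts into
    log-enrichment matrices and Shannon-entropy conservation profiles,
    designs degenerate-codon combinatorial libraries against a
    transformation-capacity budget, and compares models and crystal
    structures by Kabsch superposition and sequence identity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
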