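Package: strandbalance
Title: Mutation-Selection Balance and Multihit-Site Analysis of
    Lagging-Strand Gene Encoding in Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking why bacterial genes persist on the lagging
    strand of the replichore. Provides an analytic and stochastic
    mutation-selection balance model of strand orientation (equilibrium
    lagging-encoding probability q = u/(u+v+s)), Fitch small-parsimony
    inference of amino acid changes among closely related strains with
    exhaustive enumeration of most-parsimonious reconstructions,
    classification of alignment sites as variable, multihit, parallel or
    convergent, a conditional resampling null for the lagging:leading
    ratios of multihit-site and multihit-gene counts, Fisher's exact test
    for parallel-change gene enrichment by strand, and a synthetic-data
    generator with recorded ground-truth substitution events for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
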