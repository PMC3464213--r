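Package: famcall
Title: Family-Aware Variant Calling and De Novo Mutation Detection from
    Genotype Likelihoods
Version: 0.1.0
Authors@R:
    person("famcall", "developers", email = "famcall@example.org",
           role = c("aut", "cre"))
Description: A likelihood-based framework for joint variant site discovery,
    genotype calling and de novo point-mutation detection in pedigrees
    sequenced with short reads.  Per-site genotype likelihoods are computed
    from base pileups under an independent-error model, combined across
    family members with the Elston-Stewart peeling algorithm (with
    loop-breaking for consanguineous pedigrees), and scored against
    coalescent site priors with founder allele frequencies estimated by
    one-dimensional maximum likelihood.  De novo mutations are scored by the
    ratio of the mutation-aware to the strictly Mendelian pedigree
    likelihood.  Includes a pedigree sequencing simulator (neutral site
    frequency spectrum, gene dropping with recombination, Poisson depth,
    uniform miscalls, de novo mutation injection), evaluation metrics
    against simulated truth, a tabular genotype-likelihood format, VCF
    import/export and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
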