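Package: fdrecomb
Title: Deterministic Modifier Models for Fitness-Dependent Recombination in Diploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic multilocus recursions for the evolution of
    recombination modifiers in infinite panmictic diploid populations under
    mutation-selection balance. Implements an epistatic multiplicative fitness
    model (additive-by-additive, additive-by-dominance and
    dominance-by-dominance components), gamete production with crossover
    interference via a coefficient of coincidence, codominant recombination
    modifier alleles conferring constant or fitness-dependent (plastic)
    recombination rates, invasion and resistance tests between modifier
    alleles, a bracketing search for the optimal constant recombination rate,
    and parameter-grid scans summarising when fitness-dependent recombination
    is evolutionarily favoured.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
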