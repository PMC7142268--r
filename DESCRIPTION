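Package: lethalWF
Title: Mutation-Selection-Drift Dynamics of Lethal Disease Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and stochastic dynamics of an allele that is
    lethal when homozygous. Provides the exact one-generation recursion
    for the allele frequency in an effectively infinite population, exact
    and asymptotic mutation-selection(-overdominance) equilibria, a
    modified Wright-Fisher Markov chain appropriate for a lethal genotype
    (where selection must act on genotypes rather than alleles, and the
    adult allele frequency is bounded by one half), stationary
    distributions, distribution propagation under piecewise-constant
    dominance schedules, diffusion-approximation coefficients, and
    half-times to equilibrium after a discontinuous change in
    heterozygote fitness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
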