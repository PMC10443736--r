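Package: phasesel
Title: Evolutionary Rates under Gametophytic and Sporophytic Selection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Diffusion-approximation models of natural selection acting in
    the haploid (gametophyte) and diploid (sporophyte) phases of a
    hermaphrodite plant life cycle with mixed mating (selfing rate alpha),
    unidirectional pollen and seed flow from a mainland population, and
    genetic drift.  Computes fixation probabilities, the nonsynonymous to
    synonymous substitution-rate ratio Ka/Ks, and stationary polymorphism
    measures (pi_a, pi_s) for antagonistic and synergistic selection
    schemes, together with the exact one-generation life-cycle recursion of
    genotype frequencies and a forward Wright-Fisher simulator used as a
    stochastic cross-check.  Includes closed-form special cases,
    sensitivity analyses, and parameter-sweep utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
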