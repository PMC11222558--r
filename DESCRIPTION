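Package: noiasim
Title: Simulation of Functional QTL Effects Matching Statistical Variance Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic quantitative-genetics simulator that generates
    functional QTL effects (additive, dominance, additive-by-additive
    epistasis) such that simulated base and descendant populations realize
    user-specified statistical variance components.  Implements the NOIA
    (natural and orthogonal interactions) transforms between functional and
    statistical genetic effects for individual phenotypes in a single
    population and for plot phenotypes of three-way hybrids from two inbred
    populations; forward Wright-Fisher genome simulation with recombination;
    effect simulation by rescaled sampling of statistical effects or by a
    real-valued genetic algorithm on functional effects; genomic relationship
    matrices for additive, dominance and epistatic effects; and dense
    average-information REML for variance re-estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, vcfR, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
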