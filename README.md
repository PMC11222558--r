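# noiasim

Stochastic quantitative-genetics simulation with dominance and epistasis
that actually hits the variance components you ask for.

## The problem

Breeding-program simulators work with *functional* QTL effects — the
additive genotypic value `a`, dominance value `d` and pairwise
additive-by-additive value `(aa)` of each locus.  These are
frequency-independent properties of genotypes, which is what lets Mendelian
inheritance carry them through a breeding scheme.  But the inputs users have
are variance components estimated from *statistical* models (snpBLUP/GBLUP),
whose allele-substitution effects `α`, dominance deviations `δ` and
epistatic deviations `(αα)` are anchored to population frequencies.  With
dominance or epistasis in the model, the two parameterizations differ:

    δ = d,     (αα) = (aa),     α = a + (p − q)·d + (q_l − p_l)·(aa)

(HWE form; the package implements the general genotype-frequency form too).
Sampling functional effects naively from statistical variance inputs
therefore simulates populations with the wrong statistical variances.

`noiasim` implements the NOIA (natural and orthogonal interactions)
design-matrix transforms between the two bases, and two ways of simulating
functional effects that make a base population realize target statistical
variances:

* **`ss_noia()`** — sample statistical effects, rescale each class exactly
  onto its target, back-transform through NOIA (single populations);
* **`sf_ga_ipg()` / `sf_ga_ppg()`** — a real-valued genetic algorithm on the
  functional effects, with a variance-rescaling repair operator; required
  for three-way-hybrid plot data, where two populations contribute
  different additive variances.

Around that core: unlinked and forward Wright–Fisher (linked, drifting)
base-population generators with Haldane-model meiosis; random-mating and
three-way hybrid crop breeding schemes with single-seed-descent selfing;
phenotype simulation for individuals (`y = μ + Σt·a + Σt_d·d + Σt_ep·(aa) + e`)
and for hybrid plots from parental genotypes; variance accounting by locus
and by individual; genomic relationship matrices (additive, dominance,
Hadamard epistasis, and the generalized plot-dominance construction); and a
dense average-information REML (`aireml`) to close the loop from simulated
phenotypes back to estimated variance components.

Audience: quantitative geneticists building or validating genomic
prediction models with non-additive effects, in animal or crop breeding.

## Worked example

Simulate a 2000-QTL base population, generate functional effects meeting
statistical variance targets (400/100/100 additive/dominance/epistasis,
residual 100), breed four generations of 150 random matings × 5 offspring,
and compare the calculated descendant variances with the inputs:

```r
library(noiasim)
set.seed(1)
genome <- le_genome(2000)                  # 2000 QTL in 1000 epistatic pairs
base <- sample_base_le(100, genome)
targets <- variance_targets(additive = 400, dominance = 100,
                            epistasis = 100, residual = 100)
effects <- ss_noia(base, targets, mode = "by_locus")
variance_by_locus(attr(effects, "statistical"))
#> Variance components (statistical, by_locus):
#>  additive dominance epistasis
#>       400       100       100

pop <- run_ipg_scheme(base, mode = "le")   # generations 1-4, 3000 offspring
pheno <- simulate_phenotypes_ipg(pop, effects, sigma2_e = 100)
desc <- which(pop$generation >= 1)
sx <- reanchor_statistical(effects, pop, subset = desc)
variance_by_locus(sx)
#> Variance components (statistical, by_locus):
#>  additive dominance epistasis
#>   402.230   101.564   100.277
variance_by_individual(genetic_values(subset_population(pop, desc), sx))
#> Variance components (statistical, by_individual):
#>  additive dominance epistasis
#>   440.847   129.754   101.508
```

The base population meets the targets exactly by construction.  In the
descendants the by-locus variances stay near the inputs (frequencies barely
drift under random selection), while the by-individual dominance is inflated
by full-sib family structure — the characteristic pattern this kind of
simulation is designed to expose.  `run_experiment()` wraps the whole
replicated pipeline (effect simulation × breeding × variance calculation,
optionally REML re-estimation) for the three study designs: unlinked
individual data, linked individual data, and three-way hybrid plot data.

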