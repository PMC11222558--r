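---
title: "Simulating functional QTL effects that realize statistical variance components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating functional QTL effects that realize statistical variance components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Breeding-program simulators assign each QTL a *functional* effect — the
additive genotypic value $a_j$, the dominance value $d_j$ and, for a pair of
interacting loci, the additive-by-additive value $(aa)_{kl}$.  Functional
effects are properties of genotypes: they do not depend on allele
frequencies, which is what allows Mendelian inheritance to carry them
through a breeding scheme.  The variance components users want to prescribe,
however, come from *statistical* models fitted to real data: the allele
substitution effect $\alpha_j$, dominance deviation $\delta_j$ and epistatic
deviation $(\alpha\alpha)_{kl}$, all anchored to the allele (or genotype)
frequencies of a reference population.  With dominance or epistasis in the
model the two parameterizations differ — part of the functional dominance
and epistasis is absorbed into the substitution effects — so sampling
functional effects directly from statistical variance inputs produces
populations with the wrong statistical variances.

`noiasim` closes this gap.  It transforms between the two bases with the
NOIA (natural and orthogonal interactions) design-matrix algebra, simulates
functional effects whose implied base-population statistical variances hit
user targets exactly (or as a genetic-algorithm optimum), runs the breeding
schemes that generate descendant genotypes and phenotypes, and closes the
validation loop with genomic relationship matrices and average-information
REML.

## Models and covariates

For an individual $i$ the functional (genotypic) model is
$$y_i = \mu + \sum_j t^a_{j,i} a_j + \sum_j t^d_{j,i} d_j +
        \sum_{kl} t^a_{k,i} t^a_{l,i} (aa)_{kl} + e_i,$$
with $t^a = -1/0/1$ and $t^d = 0/1/0$ for genotypes BB/Bb/bb.  The
statistical counterpart replaces $t$ by the frequency-anchored covariates
$h$: under Hardy–Weinberg proportions $h^a = \mathrm{dosage} - 2q$ and
$h^d = (-2q^2,\, 2pq,\, -2p^2)$; in general (any genotype distribution)
$h^a = \mathrm{dosage} - p_{Bb} - 2p_{bb}$ and the three-case dominance
covariate with denominator $p_{BB} + p_{bb} - (p_{BB}-p_{bb})^2$.  The
epistatic covariate is the product of the two additive covariates.  Both $h$
forms have mean zero under their anchoring genotype distribution, and $h^a$
and $h^d$ are exactly orthogonal under it; the HWE forms have these
properties under HWE only.  The package defaults to the general
genotype-frequency form (`covariate = "genofreq"`) because descendant
generations and pooled generation sets are never exactly in HWE; the HWE
form is available as `"freq"`.

Fixed loci (drifted to $q \in \{0,1\}$) are retained with $h^a = h^d = 0$:
they contribute no variance and no transform adjustment, rather than
erroring, so descendant populations with fixation are handled uniformly.

## The NOIA transform

For a locus pair the functional and statistical effect vectors are linked by
two $9\times 6$ design matrices over the nine joint genotype classes (locus
$k$ varying fastest),
$E_s = (W_s'W_s)^{-1} W_s' W_f E_f$,
and the reverse direction swaps the roles of $W_s$ and $W_f$.  Because the
statistical columns span the same space as the functional ones, $W_f E_f$
lies in the column space of $W_s$, the left inverse is exact, and any
diagonal class-frequency weighting cancels — the package tests this
cancellation explicitly.  The same exactness gives closed forms used
throughout for speed (and cross-checked against the matrix route):
$$\delta_j = d_j,\qquad (\alpha\alpha)_{kl} = (aa)_{kl},\qquad
  \alpha_j = a_j - B_j d_j + m_{p(j)} (aa),$$
where $B_j$ is the coefficient of $t^a$ when $h^d$ is written in the basis
$\{1, t^a, t^d\}$, $m_j$ is the anchor mean of $t^a_j$, and $p(j)$ is $j$'s
interaction partner.  Under HWE both $B_j$ and $m_j$ reduce to $2q_j-1$,
recovering the familiar $\alpha = a + (p-q)d + (q_l - p_l)(aa)$.

### Three-way hybrid plots

For plot phenotypes of three-way hybrids (an inbred population-1 line
crossed to a two-way hybrid of two population-2 lines) the plot covariates
are built from the parental genotypes: the combined additive covariate
$\tfrac12(t_1 + t_2)$ with $t_2 = \tfrac12(t_{2a}+t_{2b})$ (five-level), the
plot dominance covariate $t^d_3 = (1 - t_1 t_2)/2$ (the expected
heterozygosity of the plot's plants), and the generalized statistical
dominance element $h^d_3$ anchored at the two base populations' allele
frequencies.  Plots are treated as containing infinitely many plants, so no
within-plot genotype sampling enters; a brute-force oracle that simulates
individual plot plants confirms the covariate expectations.

The pair transform uses the effect layout
$(1, a_k, a_l, a_k, a_l, d_k, d_l, (aa))$ — the additive functional effect
repeated for the two parental origins — against
$(\mu, \alpha_{k,1}, \alpha_{l,1}, \alpha_{k,2}, \alpha_{l,2},
\delta_{k,3}, \delta_{l,3}, (\alpha\alpha)_3)$.  Each locus has
$3 \times 5 = 15$ plot classes; the joint class space of a pair is therefore
$15 \times 15 = 225$, and `build_W_ppg()` constructs $225 \times 8$
matrices with the symmetric Kronecker layout (locus-$k$ class fastest).  A
15-row layout cannot carry this transform: restricting to matched classes
makes the two loci's additive columns collinear.  The closed form is
$$\alpha_{j,1} = a_j + (1 - 2q_{j,2}) d_j + (q_{p(j),1}+q_{p(j),2})(aa),$$
and symmetrically for $\alpha_{j,2}$ — the dominance adjustment uses the
*other* population's frequency because the hybrid's heterozygosity depends
on the mate's allele.

### The additive-2 scale

In the plot prediction model each plot receives the breeding values of
*both* population-2 grandparental lines through a summed incidence matrix.
The additive-2 variance component is therefore defined on the per-line-slot
scale: half the plot-level population-2 additive variance.  With fully
inbred parents and equal frequencies this makes the additive-1 to
additive-2 ratio equal the squared ratio of parent-to-plot regression
coefficients ($1$ vs $\tfrac12$), i.e. about four — the
relationship-coefficient factor that descendant populations revert to when
the optimizer's base-population structure decays.

## Variance accounting

Two conventions are implemented and tagged on every result:

* **by individual** — the population variance (divisor $n$, matching a
  within-population moment) of the summed per-individual (or per-plot)
  genetic values; absorbs between-locus covariances from linkage and family
  structure;
* **by locus** — the sum over loci (pairs) of squared effects times the
  anchor covariate variance: $2pq\alpha^2$, $4p^2q^2\delta^2$ and
  $4p_kq_kp_lq_l(\alpha\alpha)^2$ under HWE, the genotype-frequency moments
  otherwise; assumes linkage equilibrium.

Calculated descendant variances re-derive the statistical effects from the
fixed functional effects at the *descendant* frequencies: pooled
generations 1–4 genotype frequencies for individual data, and the
descendant line populations' allele frequencies for plot data.  Keeping the
base anchoring instead is available (`reanchor_statistical` with an explicit
anchor) but produces much larger between-replicate spread, because the
anchored covariates drift with the populations; the re-anchored convention
is also the one whose descendant values stay near the inputs when
frequencies barely move, which is how the validation tables behave.  The
model intercept is excluded from all variance computations.

## Simulating effects to meet targets

**Rescaled sampling (`ss_noia`).**  Prior substitution effects are drawn
$\alpha^* \sim N(0, \sigma^2_A)$; dominance degrees
$d_d \sim N(0.19, 0.097)$ (mean and *variance*; SD $\approx 0.311$ —
exposed as `dd_mean`/`dd_var`) give $\delta^* = d_d |\alpha^*|$, inducing
the directional dominance and the positive functional additive–dominance
covariance reported in the dominance-degree literature; epistatic effects
are $N(0, \sigma^2_{AA})$.  Each class is rescaled by
$\sqrt{\mathrm{target}/\mathrm{prior}}$, where the prior variance is
computed on the base population in the requested mode.  Because each of the
three statistical variance classes depends only on its own effect vector —
in both modes — a single rescaling pass is already the fixed point, and the
base-population variances equal the targets exactly.  The functional
effects are then obtained by the backward NOIA transform at base
frequencies.  In the plot setting the backward transform would return two
different functional additive effects per QTL, contradicting the assumption
that functional effects are population-independent, so `ss_noia` rejects
pPG targets.

**Genetic algorithm (`sf_ga_ipg`, `sf_ga_ppg`).**  A real-valued GA over
the concatenated $(a, d_d, (aa))$ vector: tournament selection (size 3),
BLX-0.5 blend crossover (probability 0.8), per-gene Gaussian mutation
(rate 0.1, SD 10% of the class prior SD), 5% elitism, and a convergence
tolerance of 0.1% of the summed targets — hyperparameters are not dictated
by the method and are all exposed in `ga_control()`.  Offspring may
additionally pass through a *variance-rescaling repair operator* (a memetic
local-search step): the epistatic and dominance classes scale exactly onto
their targets, and the additive class scale solves a quadratic (single
population) or a one-dimensional search (plot setting, where two additive
targets share one scale).  With the repair enabled the single-population
search typically converges in generation 0 — the rescaling is exact there —
while the plot setting still requires genuine evolution, because no global
scaling can move the additive-1/additive-2 *ratio*; the GA achieves that
through recombination of per-locus effect patterns.  Disabling
`local_search` yields a plain GA, which improves steadily but needs far
larger budgets.  By-locus scaling in the plot setting is rejected: with
mildly diverged base populations the per-locus covariate-variance ratio is
essentially constant near the relationship factor, so no functional-effect
set can satisfy a different ratio locus by locus (a one-locus exhaustive
scan in the test suite shows the infeasibility directly).

## Genome and breeding simulation

Base populations come in two flavours.  The unlinked generator samples
per-locus target frequencies from U(0.05, 0.95) and haplotype alleles
binomially (linkage equilibrium, HWE in expectation).  The linked generator
runs a forward Wright–Fisher history: all loci start at frequency 0.5,
discrete generations reproduce by random union of recombinant gametes, and
after the historical phase QTL are drawn from loci with MAF ≥ 0.05 (optionally
paired at random, one pair per QTL).  Meiosis uses the Haldane model —
Poisson crossover counts per chromosome (length/100), uniform positions, no
interference, starting haplotype by fair coin; unlinked mode inherits each
locus independently.  Because the Haldane process has no interference, the
inheritance law restricted to the QTL subset equals its marginal law, so
descendants are bred on the QTL-only map after QTL are drawn (`keep_qtl`)
without approximation.  There is no mutation or selection anywhere: drift
is the only force, and neutrality of the schemes is tested.

The individual-data scheme mates randomly selected parents (150 matings of
5 offspring for 4 generations by default); when a generation offers fewer
candidates than the nominal parent count — as the 100-individual base does —
all candidates are used.  The three-way scheme breeds two line populations
in parallel (within-population crosses, 5 seeds per cross, then 4 rounds of
single-seed-descent selfing, giving pedigree-expected inbreeding
$1-2^{-4} = 0.9375$), produces two-way hybrids by random mating of
generation-$t$ with generation-$(t-1)$ population-2 lines, and crosses 200
population-1 lines with 100 two-way hybrids (5 and 10 matings each, one
plot per mating, 1000 plots per generation in generations 2–4).  A base
plot set built from the base lines (each base-1 line in 5 matings) feeds
the GA fitness.

What the generator emulates — and what it does not.  Drift-generated LD,
family structure, inbreeding under selfing and frequency divergence between
populations are all real features of the data the statistical models face.
Mutation–drift equilibrium at realistic effective sizes, a literature
genetic map beyond configurable chromosome counts/lengths, selection, and
genotype-by-environment structure are not emulated; passing tests therefore
validate the effect-simulation algebra and the drift behaviour of the
schemes, not fidelity to any real crop or livestock genome.

### Problem sizes

The validation experiments run at desk scale, chosen once: the unlinked
example at the published size (2000 QTL, 1000 pairs, 100 base individuals,
3000 descendants; 10 effect × 2 scheme replicates); the linked example with
a 7-chromosome, 230 cM genome of 800 loci per
chromosome and a
200-generation, $n=100$ history (the published history is far longer and
denser; LD levels at desk scale are not calibrated to it, which the
package exposes as knobs); the three-way example with 300 loci per
chromosome, 800 QTL, a 100-generation common history at $n=200$ and a mild
20-generation divergence, with the breeding scheme itself at the published
sizes.  Divergence is kept mild deliberately: strong divergence changes the
structure of the optimization problem (per-locus ratio tilting becomes
feasible and persists in descendants) and is not the regime the method
addresses.

## Estimation loop

`build_grms_ipg` constructs $G_A$ from $h^a$ covariates, $G_D$ from the
general $h^d$ covariates (each cross-product trace-normalized to mean
diagonal 1) and $G_{AA}$ as the trace-normalized Hadamard square of $G_A$;
anchor frequencies default to the observed frequencies of the analyzed
individuals, as in standard GBLUP practice, with truth-tracking anchors
available separately.  The plot-model set adds $G_{A1}$, $G_{A2}$ from the
parental line genotypes, $G_{D3}$ from $h^d_3$, and $G_{AA3}$ from the
parental-line genotype means
$h^a_3 = \tfrac12(t_1 - 2q_1) + \tfrac14(t_{2a}+t_{2b}-4q_2)$, plus the
incidence matrices (one population-1 slot, two summed population-2 slots
per plot).

`aireml` maximizes the restricted likelihood of
$y = \mathbf 1\mu + \sum_c Z_c g_c + e$ with dense algebra:
average-information updates with step halving whenever a step would leave
the parameter space or decrease the restricted log-likelihood, a small
positive floor as the boundary constraint, diagonal bending
($10^{-6} \times$ mean diagonal) for structures whose Cholesky fails,
equal-split starting values, convergence on $|\Delta \log L| < 10^{-6}$,
and asymptotic SEs from the inverse AI matrix.  Traces are computed from
the explicit $V^{-1}$ with the rank-one fixed-effect correction, so each
iteration costs one Cholesky inversion plus elementwise products — adequate
for the $n \le 3000$ designs the package targets (a configurable cap
guards against accidentally dense-solving much larger problems).  The
implementation is checked against an independent direct optimization of
the restricted likelihood on small data, and against simulated truth at
full scale.

A caution on the multi-component fits at reduced record counts: the
dominance, epistasis and residual components compete through relationship
matrices that are close to identity off the family blocks, so individual
replicates can push the epistasis component to the zero boundary and move
its variance into the residual.  The replicated validation therefore reads
the characteristic pattern — dominance estimated above its input, residual
below — from replicate medians; at the full record counts the components
separate and the same pattern shows in the means.

## Known limitations

Only additive-by-additive pairwise epistasis with each QTL in at most one
pair; no additive-by-dominance or higher-order terms; no mutation,
selection, multi-allelic QTL or genotype-by-environment interaction; dense
REML only; by-locus variance ignores LD by construction (the by-individual
route exists precisely to expose that gap, and the discrepancy between the
two in linked genomes is a finding, not an error).
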