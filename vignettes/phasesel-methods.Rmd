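---
title: "Methods: biphasic selection, mixed mating and molecular rates"
author: "phasesel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biphasic selection, mixed mating and molecular rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasesel)
```

## The model

`phasesel` models one biallelic autosomal site (ancestral allele A,
mutant a) in a hermaphrodite plant population of census size $N$ on an
island that receives unidirectional gene flow from a large, genetically
stable mainland. One generation runs through a fixed sequence of events:
gamete production, pollen flow (rate $m_P$, migrant mutant frequency
$Q_a$; ovules do not migrate), gametophytic selection, mixed mating
(selfing rate $\alpha$), seed flow (rate $m_S$, migrants at
Hardy–Weinberg proportions), sporophytic selection, and finally genetic
drift.

Selection acts twice. In the haploid gametophyte phase gamete fitnesses
are $(w_A, w_a) = (1-s_h, 1)$ under the antagonistic scheme and
$(1, 1-s_h)$ under the synergistic scheme; in the diploid sporophyte
phase genotype fitnesses are $(1, 1-h s_d, 1-s_d)$ in both schemes.
A single signed coefficient ($+s_h$ antagonistic, $-s_h$ synergistic)
carries the scheme through every formula.

Mixed mating enters through three derived quantities: the single-locus
equilibrium inbreeding coefficient $F = \alpha/(2-\alpha)$, the
effective size $N_e = N/(1+F) = (1-\alpha/2)N$ (complete selfing halves
$N_e$), and the composite migration rate
$\tilde m = m_S + \frac{1-\alpha}{2} m_P$: selfed ovules are never
fertilised by immigrant pollen, so pollen flow is discounted by the
outcrossing fraction while seed flow is not — which is why seed flow has
the larger effect at equal rates.

### Two layers: exact recursion and diffusion

The package keeps two representations of the same life cycle.

The *exact recursion* (`full_generation()`) tracks genotype — not just
allele — frequencies through every stage, so selfing-generated
departures from Hardy–Weinberg are represented without assuming
equilibrium $F$. In the outcrossing fraction, selected pollen and ovule
pools unite at random; in the selfing fraction homozygous parents breed
true while gametophytic selection inside heterozygous parents sets the
gamete ratio to $w_A : w_a$ (normalised), offspring following the
squared ratios; the parental mean gamete fitness there is $1-s_h/2$.

The *diffusion layer* uses the first-order systematic change
(`systematic_change()`)
$$M(p_a) = \tilde m (Q_a - p_a) + s_h p_A p_a\Big(1-\tfrac{\alpha}{2}(1+F)\Big)
 - s_d p_A p_a\Big(p_a + \tfrac{\alpha}{2}p_A(1+F) + h(p_A-p_a)\big(1-\tfrac{\alpha}{2}(1+F)\big)\Big)$$
together with drift variance $V = p_a(1-p_a)/(2N_e)$. The test suite
verifies, over a grid of frequencies, dominance values and mating
systems, that the recursion's per-generation change equals $M$ up to a
fixed multiple of $(s_h+s_d+\tilde m)^2$ — the recursion is the ground
truth, $M$ its first-order shadow.

### Fixation, Ka/Ks, and stationary polymorphism

The fixation probability of the mutant from frequency $p_0$ is
$\varphi(p_0) = \int_0^{p_0} G / \int_0^1 G$ with
$G(p) = \exp(-2\int M/V\,dp)$, which evaluates to
$$G(p) = p^{-cQ_a}(1-p)^{-cQ_A}
 \exp\!\big(B_2 p^2 + B_1 p\big),\qquad c = 2(2-\alpha)N\tilde m,$$
$B_2 = 2(1-\alpha)(1-2h)N s_d$, and
$B_1 = 2N\big((\alpha+2(1-\alpha)h)s_d - 2(1-\alpha)s_h\big)$.
Substitution rates are $K_a = 2N_e u\,\varphi(p_0)$ and
$K_s = 2N_e\mu\,\varphi_0(p_0)$, so
$K_a/K_s = (\varphi/\varphi_0)(u/\mu)$. Stationary polymorphism under
migration–selection–drift balance uses Wright's density
$\phi(p) \propto p^{cQ_a-1}(1-p)^{cQ_A-1}e^{-B_2p^2-B_1p}$, giving
$\pi_a = \int 2p(1-p)\phi\,dp$ and, at the neutral site, the closed form
$\pi_s = 2Q_AQ_a\big(1-\tfrac{1}{1+c}\big)$.

In the additive isolated cases ($h=1/2$, $\tilde m=0$) all ratios reduce
to $\frac{1-e^{kp_0}}{(1-e^k)p_0}$ with a case-specific rate $k$
(`closed_form_ka_ks()`), and the antagonistic biphasic case balances
exactly at $s_d = 2(1-\alpha)s_h$, i.e. at the selfing rate
$\alpha^\* = 1 - s_d/(2s_h)$ (`balancing_selfing_rate()`). The same
convention as in those derivations — the neutral comparison allele
starts at the same $p_0$ — is used throughout.

## Numerical choices

**Quadrature.** Every diffusion integrand factors as a Beta kernel
$p^{a-1}(1-p)^{b-1}$ times a smooth exponential of a quadratic. We
integrate with an $n$-point Gauss–Jacobi rule (default $n=120$) matched
to the exact endpoint exponents, computed by the Golub–Welsch
eigenvalue method; partial integrals $\int_0^{p_0}$ substitute
$p = p_0 t$ so only the left singularity stays active. This is exact for
polynomial smooth factors up to degree $2n-1$ and reaches ~1e-13
agreement with adaptive reference quadrature in the tests; naive
adaptive rules are what fail near the integrability boundary.
Exponentials are shifted by their maximum exponent before
exponentiation to avoid overflow at large $N s$.

**Integrability.** $\int G$ diverges as soon as an endpoint exponent
$c\,Q \ge 1$. The bound is checked in closed form *before* integrating
and violated settings raise a structured `nonintegrable` error naming
the offending endpoint — at the example settings ($N=30$,
$\alpha=0.05$, $Q_a=0.5$) this happens for $m_P \gtrsim 0.036$, and
sweep rows past the bound carry flags rather than silent numbers. The
stationary density instead requires $c>0$; with $\tilde m = 0$
polymorphism is transient and `pi_s()` returns 0 with a
`transient` flag rather than normalising a non-normalisable density.

**Neutral solution.** $\varphi_0$ is the regularised incomplete Beta
function `pbeta(p0, 1-cQa, 1-cQA)` (exact); the quadrature path is kept
and cross-validated against it to 1e-8 in the tests.

**Removable singularities.** The closed forms at $k \to 0$ (complete
offset, neutrality) return the analytic limit 1; `expm1()` keeps the
small-$k$ evaluations accurate.

**Sensitivities.** Closed-form derivatives exist only in special cases,
so `kaks_sensitivity()` uses central differences with one Richardson
step (relative step $10^{-3}$, combining $h$ and $h/2$ to fourth
order); perturbed models bypass the constructor's integer-$N$ and
sign checks because the diffusion formulas are continuous in every
parameter.

**Default $p_0$ and mutation rates.** $p_0$ defaults to $1/(2N)$ (a
single new copy) and $u=\mu=10^{-8}$ per site per generation, a typical
plant nuclear point-mutation order; only $K_a$ and $K_s$ levels depend
on the absolute rate, never the ratio.

## The Wright–Fisher oracle

`wf_fixation()` and `wf_stationary()` simulate the identical life
cycle forward in time: each generation applies the deterministic
recursion and then draws $N$ adult genotypes multinomially (decomposed
into two vectorised binomials so $2\times10^5$ replicates advance in
parallel; the four standard fixation settings take a few seconds each).
Drift is applied at the census size after the selfing-structured mating
step, so the $N_e = (1-\alpha/2)N$ reduction emerges from the mating
structure rather than being imposed — agreement with the diffusion is
asserted empirically, within three binomial standard errors at 200,000
replicates for fixation fractions, and within three between-replicate
standard errors for stationary moments (burn-in $10N$ generations,
thinning $N$, independent chains so the errors are valid despite
autocorrelation). Initial mutants are placed as heterozygotes
($\mathrm{round}(2Np_0)$ copies, homozygotes only when copies exceed
$N$). Reproducibility is bit-for-bit at a fixed seed.

What the oracle emulates — and what it does not: it realises exactly the
modelled single-site life cycle (event order, mainland stability,
equal pollen/ovule allele fitness, no mutation recurrence within a
trajectory). Passing tests therefore validate the diffusion *under the
model's own assumptions*; they say nothing about linkage, background
selection, sex-differential gamete fitness, overlapping generations or
seed banks, which real data may contain and the theory deliberately
excludes.

## Design decisions taken where the model description is open

- **Migrant seed genotypes** are taken at Hardy–Weinberg proportions
  $(Q_A^2, 2Q_AQ_a, Q_a^2)$ — the simplest composition consistent with a
  large, stable, randomly mating mainland. Whether migrant seeds should
  carry mainland inbreeding is left open; a non-HW mainland would enter
  only through the seed-flow mixing step.
- **Selfed plants use their own pollen**: pollen flow affects only the
  outcrossing fraction. This is precisely what gives $\tilde m$ its
  $(1-\alpha)/2$ pollen discount, and the recursion and the diffusion
  agree on it by construction.
- **Parameter validation is eager but weak selection is advisory**: the
  illustrative settings themselves use $s \le 0.06$ with $N = 30$
  ($Ns \approx 1.8$), so coefficients above 0.1 warn rather than error.
- **$N_e$ stays real-valued** (it enters only continuous formulas);
  census $N$ must be a positive integer because the simulator samples
  $N$ individuals.
- **Sign-flip construction**: the synergistic scheme is the
  antagonistic scheme with $s_h \mapsto -s_h$ in every diffusion
  formula. For the exact recursion the flip holds to first order only
  (gamete fitness $1-s_h$ versus $1/(1+s_h)$ differ at $O(s_h^2)$),
  and the tests assert exactly that.
- **The equilibrium $F$–$\alpha$ relation** is the single-locus
  approximation; transient $F$ dynamics are not modelled, but the
  recursion tracks genotypes so departures from equilibrium decay
  naturally under iteration.

## Problem sizes used in verification

The test suite runs the closed-form/quadrature grids at $N$ = 20–60,
Wright–Fisher fixation checks at 200,000 replicates per selection
scheme ($N=30$, $p_0 = 1/60$), stationary-moment checks at 150–200
independent chains of ~1,600 generations, and the figure-style sweep
contracts on 51-point grids. These sizes give Monte-Carlo standard
errors small enough that a systematic error of a few percent in the
diffusion would be detected, while the whole suite completes in well
under a minute.

## Known limitations

Single site, no linkage disequilibrium or background selection; no
mutational influx at stationarity (the density conditions on
segregating variation maintained by migration, so $\pi_s = 0$ without
gene flow); equal allele fitness in pollen and ovules; weak selection
of the same order as migration and drift ($O(s^2)$ terms are dropped in
the diffusion layer, with the discrepancy bounded empirically by the
recursion tests); the mainland is static. The non-integrable
high-migration regime is reported as such rather than extrapolated.
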