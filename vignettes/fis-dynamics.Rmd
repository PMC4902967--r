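---
title: "Methods: the genotype-state Markov chain behind fisdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the genotype-state Markov chain behind fisdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fisdyn)
```

## The model

`fisdyn` follows one selectively neutral locus with $n$ alleles in a
closed population of constant size $N$ (diploid, monoecious ramets,
non-overlapping generations). The population's configuration at a
generation is the vector of counts of individuals over the
$g = n(n+1)/2$ unordered genotypes; the set of such vectors — the
compositions of $N$ into $g$ parts, $\binom{N+g-1}{g-1}$ of them — is the
state space of a discrete-time Markov chain. Working at the genotypic
rather than the allelic level is the point: under partial clonality
Hardy–Weinberg proportions cannot be assumed, so allele frequencies do not
determine genotype frequencies.

One generation composes three operations on the genotype frequency vector
$\nu = q/N$:

1. **Mutation** ($\nu \mapsto \nu_I$). Each allele copy independently
   keeps its state with probability $\alpha = 1-\mu$ and becomes one
   specific other allele with probability $\beta = \mu/(n-1)$ (the
   symmetric $k$-alleles scheme). On unordered genotypes this is a linear
   map, exposed as `mutation_operator()`; the unit tests verify it against
   an independent construction that expands genotypes to ordered allele
   pairs, applies the $n \times n$ substitution matrix to each slot, and
   re-collapses.
2. **Reproduction** ($\nu_I \mapsto \nu_{III}$). A fraction $c$ of
   offspring copy a parent drawn at random (clonal); the remaining $1-c$
   are formed from random union of gametes, i.e. Hardy–Weinberg
   proportions $p_i^2, 2p_ip_j$ of the post-mutation allele frequencies
   $p_i = \nu_{ii,I} + \tfrac12\sum_{j\neq i}\nu_{ij,I}$. Selfing occurs
   at the random-mating rate $1/N$ and is not modelled separately.
3. **Drift**. The next state is a multinomial draw of $N$ individuals
   from $\nu_{III}$. The transition probability between any two states is
   the corresponding multinomial pmf, and stacking them per current state
   gives a **column-stochastic** matrix $M$ (current state per column —
   deliberately documented everywhere, since most texts use the row
   convention).

Distribution propagation is $x_t = M^t x_0$; the stationary distribution
is the dominant eigenvector of $M$; and every question about
$F_{IS} = (H_e - H_o)/H_e$ becomes a functional of $x_t$ via the per-state
descriptor table (`describe_states()`).

## Parameters and defaults

| Parameter | Meaning | Range / default |
|---|---|---|
| `N` | ramets per population (constant) | positive integer |
| `c` | clonal fraction of offspring per generation | $[0,1]$ |
| `mu` | per-allele mutation rate per generation | $[0,(n-1)/n]$ |
| `n_alleles` | alleles at the locus | $\ge 2$, default 2 |
| `epsilon` | acceptable error for convergence criteria | default $1/(2N)$ |
| `cap` | largest state space materialised | default $2\times10^6$ |

$\varepsilon = 1/(2N)$ is half the smallest genotype-frequency change an
exhaustive census of $N$ diploids could register, which makes convergence
statements commensurate with what is measurable in the population itself.
The cap reflects that exact work beyond a few million states buys little:
the Monte Carlo path (`simulate_loci()`) has no cap.

## Convergence-time theory

Deviations from the steady state decay geometrically under reproduction
alone (factor $c$) and under mutation alone (factor $1-\mu n/(n-1)$),
giving the closed forms

$$t_c = 1 + \frac{\log\varepsilon}{\log c}, \qquad
  t_\mu = 1 + \frac{\log\varepsilon}{\log\left(1-\mu\frac{n}{n-1}\right)},$$

with $t_c = 1$ at $c=0$, $t_c = \infty$ at $c=1$, and $t_\mu = 1$ at the
degenerate rate $\mu = (n-1)/n$. Both are real-valued; whole-generation
reporting uses the ceiling, and a $\pm 1$ generation discrepancy against
tabulations that round differently is expected. Genetic drift admits no
closed form; `absorption_profile()` solves the expected first-passage time
to genotypic uniformity (the absorbing set of the $c=1,\mu=0$ chain:
states with a single genotype left, ending either in allele fixation or in
a pure heterozygote line with $F_{IS}=-1$) exactly from the standard
linear system on the transient states, and `fit_drift_law()` fits
$t_N = \sigma N - \tau$ through those exact times. The default fitting
grid is $N \in \{10,20,\dots,50\}$ for two alleles — the fit there is
essentially exact ($R^2 > 0.999$) and extrapolates to the $N=100$ value
computed directly in the acceptance checks — and a smaller grid for three
alleles, where the state space grows as $N^5$.

The dominant process at a parameter set is the argmin of
$(t_c, t_\mu, t_N)$. Boundary curves between dominance regions follow from
*exact equality of the implemented formulas*: $t_c = t_\mu$ at
$c = 1 - \mu n/(n-1)$ and $t_c = t_N$ at
$c = \varepsilon^{1/(t_N-1)}$. An alternative printed algebra of these
boundaries circulates ($c = \mu n/(n-1)$; Euler's $e$ in place of
$\varepsilon$); it is inconsistent with the time formulas it is meant to
equate, and the derived forms are the ones that reproduce the numeric
anchors (e.g. the reproduction/drift crossover near $c \approx 0.97$ for
$N = 100$). Both forms are nevertheless exposed through the
`phase_boundary_*()` functions (`form = "derived"` / `"printed"`) so the
discrepancy can be inspected rather than taken on faith.

## The equilibrium reference model

For comparison with earlier equilibrium theory, `equilibrium_fis()`
implements the closed-form mean
$$\bar F_{IS,\infty} = \frac{1}{(2N-1) - 2N/(c(1-\mu)^2)},$$
the single-population specialisation (within-group common-origin
probability 1, between-group 0, selfing at $1/N$) of a metapopulation
identity recursion, together with its algebraic inversion for $c$
(`infer_clonality()`) and the two-variable recursion on
$F = 1-H_o$, $\Theta = 1-H_e$ (`balloux_step()`). Two derivation notes:

* The denominator groups as $(2N-1) - 2N/(c(1-\mu)^2)$. The alternative
  reading $(2N/c)\cdot(1-\mu)^2$ reproduces neither the $c\to1,\mu\to0$
  limit of $-1$ nor any of the numeric anchors, so it is rejected.
* In the affine recursion, the intercept entry belonging to $F$ is
  $(1-c)/(2N)$, not $(1-c)/N$: a sexual offspring selfs with probability
  $1/N$ and is then identical-by-state with probability $(1+F)/2$, which
  splits into $(1-c)/(2N)$ on the $F$ coefficient and the same constant
  term. With this intercept the recursion's fixed point agrees with the
  closed form to machine precision over the whole $(c,\mu,N)$ grid (a
  tested invariant); with $(1-c)/N$ the fixed-point $F_{IS}$ falls below
  $-1$, which is impossible.

The reference model assumes *infinite alleles*: every mutation creates a
novel allele and heterozygosity is only ever created, never restored by
back mutation. The finite $k$-alleles chain behaves differently as soon
as $\mu$ is large relative to $1/N$: back mutation pushes allele
frequencies toward isoplethy and $F_{IS}$ toward zero, so the chain's
stationary mean is much closer to 0 than the closed form at the same
parameters. The test suite pins this divergence explicitly; it is a
documented model difference, not a defect of either formula.

* The recursion's convergence time `balloux_time()` defaults to the start
  $F_0 = \Theta_0 = 0.5$, matching the biallelic isoplethic
  Hardy–Weinberg preset ($H_o = H_e = 0.5$); no canonical start convention
  exists, so this choice is stated rather than inherited.

## Numerical choices

* **Multinomial pmf in log space.** $N!$ overflows double precision at
  $N \approx 171$; all pmfs are assembled as
  $\exp(\log\Gamma\text{-coefficient} + \sum q\log\nu)$, with exact zeros
  handled by masking (a target state requiring a genotype of probability
  zero gets probability exactly 0, never `NaN`).
* **State order.** Genotypes are ordered by allele pairs $(i \le j)$
  lexicographically; states colexicographically (the count of the last
  genotype class is the most significant digit). Any deterministic order
  would do — this one admits a closed-form rank (`state_index()`), so
  index lookups need no table.
* **Stationary distribution.** Power iteration (successive-iterate total
  variation below $10^{-12}$) is the default; a direct null-space solve of
  $M - I$ with the normalisation row is the cross-check, and the two must
  agree to $10^{-8}$ on every test chain. The reducible drift-only chain
  is rejected with a pointer to the absorption analysis instead of
  returning one of its infinitely many stationary vectors.
* **Mixing time.** Worst case over all pure start states of the total
  variation distance to the stationary distribution, thresholded at
  $\varepsilon = 1/(2N)$. TV is the standard chain-mixing metric, and
  reusing $\varepsilon$ keeps one notion of "converged" across the
  package. $t_N$ is deliberately *not* an $\varepsilon$-criterion but the
  maximal expected absorption time — absorption is exact, so no threshold
  is needed.
* **Undefined $F_{IS}$.** At fixation $H_e = 0$ and $F_{IS}$ does not
  exist; it is carried as `NA` plus an explicit `fixed` flag, and every
  summary conditions on the non-excluded states and renormalises, so no
  `NaN` arithmetic can leak into means. Exact-chain summaries exclude only
  fixed states by default; the multilocus sampling path excludes
  *near-fixed* states (top allele frequency above $1-\sqrt{1/(2N)}$) by
  default, because that is what empirical surveys do with
  near-monomorphic markers. The flag is shared (`exclude =`).
* **Isoplethic presets with indivisible $N$.** The whole rounding
  remainder goes onto heterozygote classes (cyclically), because a
  heterozygote adds half a copy of two alleles and therefore preserves
  equal allele frequencies exactly; a warning records the rounding.
* **Floating point guards.** Frequency entries in $(-10^{-15}, 0)$ are
  clamped to zero before multinomial use; weighted quantiles are
  left-continuous inverses of the discrete cdf with a $10^{-12}$ slack on
  the cumulative weights.

## What the Monte Carlo simulator does and does not emulate

`simulate_loci()` draws each locus independently through the exact
generation cycle, using R's base Mersenne–Twister generator with a single
recorded integer seed; runs are bit-reproducible given
(parameters, start, `n_loci`, `seed`), which the tests assert, and the
multinomial draws use a conditional-binomial decomposition vectorised
across loci. Agreement with the exact chain is verified distributionally
(chi-squared on state occupancy of the 10-state $N=3$ system after three
generations).

The simulator (and the exact chain) encode *idealised* survey conditions:
unlinked loci that are exchangeable replicates of one process, exhaustive
sampling of all $N$ ramets, no genotyping error, no null alleles, constant
$N$, constant $c$ and $\mu$, no selection, no gene conversion, no
migration, non-overlapping generations. Passing tests therefore say the
implementation matches the model, not that the model exhausts real data:
linkage, partial sampling and scoring artefacts all *add* variance to
multilocus $\bar F_{IS}$ estimates, so the sampling-deviation results here
are conservative lower bounds on real-world estimation error.

## Problem sizes

The package's own test and acceptance computations run at the sizes the
questions demand and no larger: exact-chain cross-checks on $N \le 10$
(6–231 states), where brute-force oracles (path enumeration, term-by-term
pmf evaluation, null-space solves) are feasible; the biallelic $N = 100$
chain (5151 states) for the stationary-mean, absorption and
sampling-deviation anchors; $10^5$ multilocus samples of $L = 10$ loci for
the deviation analysis; and $2\times10^4$ simulated loci for the
chi-squared comparison. The drift-law fit uses exact absorption times on
$N \in \{10,\dots,50\}$ (two alleles), where the linear law already holds
to $R^2 > 0.999$.

## Known limitations

* Mutation is the symmetric $k$-alleles scheme; unequal per-pair rates
  are not implemented (the isoplethic steady state would survive constant
  unequal rates, but the linear operator as implemented is symmetric).
* Dense matrices only: memory grows as the square of the state count
  (the 5151-state biallelic $N=100$ matrix is ~212 MB of doubles), which
  is why enumeration is capped and larger systems route to Monte Carlo.
* No analytic $\sigma(n), \tau(n)$: the drift law is a numerical fit, and
  extrapolation far beyond the fitted $N$ range inherits its risk.
* The multilocus machinery samples loci i.i.d. from a single-locus
  distribution; linked loci and locus-specific parameters are out of
  scope.
* No metapopulation structure: the general metapopulation form of the
  reference model is present only as an internal, fixed to the
  single-population specialisation.
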