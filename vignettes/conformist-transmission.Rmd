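---
title: "Conformist transmission: learning rules, a statistical test, and the evolution of conformity in metapopulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformist transmission: learning rules, a statistical test, and the evolution of conformity in metapopulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformity)
```

## The scientific problem

Conformist transmission is social learning in which the most common
behavioural variant is adopted *disproportionately* more often than under
random copying: the response curve mapping the demonstrator frequency $q$
of a variant to the probability $p(q)$ of adopting it lies above the
diagonal for $q > 1/2$. This package provides three connected tools:

1. a family of **frequency-dependent learning rules** flexible enough to
   express hyper-conformity, weak conformity and anti-conformity with a
   single parameter;
2. a **statistical test** for conformist bias in choice-frequency data,
   with a synthetic-data generator and a calibration/power harness;
3. a **forward-time metapopulation simulator** showing how conformist mate
   choice can evolve, without any direct fitness benefit, through Fisher
   runaway processes running independently in subpopulations coupled by
   dispersal.

## Learning rules

The classical three-demonstrator conformist rule is the cubic

$$p(q) = q + D\,q(1-q)(2q-1), \qquad D \in [0,1],$$

whose bias strength $D$ is bounded by the small demonstrator sample: at
$D = 1$ it equals majority-of-three copying, $q^3 + 3q^2(1-q)$, and it
cannot produce steep, step-like responses around $q = 1/2$. The package's
central rule is instead the logistic (discrete-choice) form

$$p(q) = \frac{q^\beta}{q^\beta + (1-q)^\beta},$$

with a real conformity strength $\beta$:

* $\beta > 1$ — hyper-conformity (conformist transmission in the classical
  sense);
* $\beta = 1$ — unbiased copying, $p(q) = q$;
* $0 < \beta < 1$ — weak conformity (majority bias attenuated);
* $\beta < 0$ — anti-conformity ($\beta = 0$ is the uniform-random
  boundary, flagged by `classify_regime()`).

The rule has a random-utility micro-foundation: a learner choosing the
trait $j$ that maximises $\ln q_j + \varepsilon_j/\beta$ with i.i.d.
standard Gumbel noise $\varepsilon_j$ adopts trait $j$ with probability
$q_j^\beta / \sum_k q_k^\beta$. This is exactly the multi-trait extension
implemented by `multi_logistic_probs()`, and `sample_choice()` draws
choices by that mechanism directly — never through the closed form — so it
doubles as an independent Monte-Carlo oracle in the test suite.

Real learners also depart from unanimous majorities. The error-mixture
extension draws a uniformly random trait with probability $\alpha$ and
applies the conformist rule otherwise; with two traits

$$p'(q) = \frac{\alpha}{2} + (1-\alpha)\,\frac{q^\beta}{q^\beta+(1-q)^\beta},$$

which plateaus at $1 - \alpha/2$ under unanimity. With $K$ traits we
generalise the random component to uniform over all $K$ options
($\alpha/K$); this is our extension — the two-trait mixture is the stated
model, the $K$-trait version follows the same logic.

```{r rules}
logistic_prob(0.6, logistic_rule(beta = 2.8))
logistic_prob(1.0, logistic_rule(beta = 3, alpha = 0.1)) # plateau 1 - alpha/2
classify_regime(2.8)
```

### Numerical choices

* $p(q)$ is evaluated in logit form
  $1/(1+e^{-\beta(\ln q - \ln(1-q))})$ (and the $K$-trait version as a
  log-space softmax with max subtraction), so $|\beta|$ in the thousands
  cannot overflow.
* Endpoints are resolved by continuity for $\beta > 0$ ($p(0)=0$,
  $p(1)=1$, then mixed with $\alpha$). For $\beta \le 0$ the limit at
  unanimity diverges, so `q` of 0 or 1 raises an explicit degenerate-input
  error rather than returning a silent limit.

## The conformity test

Taking log odds of the logistic rule gives a linear relationship through
the origin,

$$\ln\frac{p(q)}{1-p(q)} = \beta\,\ln\frac{q}{1-q},$$

so $\beta$ is estimable from grouped choice-frequency data by a
through-origin regression of empirical response log odds on demonstrator
log odds, and a one-sided test of $\beta > 1$ (t reference with
$\text{points}-1$ degrees of freedom) is the test for conformist bias.
With $K$ traits, any pair $(A, B)$ satisfies
$\ln(p_A/p_B) = \beta \ln(q_A/q_B)$; `fit_beta_multitrait()` pools all
unordered within-group pairs, each taken once in a fixed alphabetical
ordering so that using both orderings cannot pseudo-replicate the data.

Three design choices were genuinely open and are resolved as follows:

* **Weighting.** The empirical logit of a binomial proportion has
  approximate sampling variance $1/(n\,\hat p(1-\hat p))$, which varies by
  an order of magnitude across a typical design. The default is therefore
  inverse-variance ("binomial") weighting; in our calibration harness
  (9 frequency levels $\times$ 200 observers, 4000 null replicates) the
  unweighted test rejects a true $\beta = 1$ at roughly twice its nominal
  5% level, while the weighted test stays below it. Plain OLS remains
  available (`weighting = "ols"`); the two coincide exactly on noiseless
  data.
* **Unanimity.** Observed proportions of 0 or 1 have infinite log odds.
  The default applies the Haldane–Anscombe continuity correction (+0.5 to
  counts, +1 to totals) *only to the affected rows*, so exact interior
  data are untouched; `unanimity = "drop"` removes such rows instead.
  Which policy was used is recorded in the returned `beta_estimate`.
* **Intercept.** The model has none; a free intercept can be requested as
  a diagnostic for miscalibrated data.

For data with error-driven departures from unanimity the regression is
biased toward false negatives, so `fit_error_mixture()` fits
$(\alpha, \beta)$ jointly by maximising the binomial likelihood
(box-constrained quasi-Newton from several starts; observed-information
standard errors; boundary estimates flagged, not silently accepted). The
mixture nests the pure rule at $\alpha = 0$ and handles $q \in \{0, 1\}$
groups directly through the plateau. It needs at least three distinct
frequency levels, at least one outside $\{0, \tfrac12, 1\}$ — levels in
that set carry no information about $\beta$.

```{r fit}
tab <- simulate_choices(logistic_rule(beta = 2, alpha = 0),
                        freq_levels = seq(0.1, 0.9, 0.1),
                        observers = 200, seed = 1)
fit_beta_binary(tab)
```

`power_study()` wraps this loop: the $\beta = 1$ row estimates the type-I
error, the rest trace the power curve.

## The metapopulation simulator

The simulator formalises a gene–culture runaway argument. Individuals are
haploid carriers of two unlinked diallelic loci: a display trait (A/B)
expressed in males only and neutral for fitness, and a preference locus
(C/c) expressed in females only. `c` females mate with a uniformly random
local male; `C` females apply the logistic conformist rule with strength
$\beta$ to their perceived local frequency $q$ of A males, draw a target
trait, and mate with a random local male of that trait. Conformity carries
no direct cost. Each female leaves exactly one son and one daughter, so
population size and the 1:1 sex ratio are exactly conserved;
generations do not overlap. Offspring inherit, with probability $1-r$,
both alleles from one uniformly chosen parent, and with probability $r$
(recombination) the trait allele from one parent and the preference
allele from the other. A fraction $d$ of offspring then disperses:
migrants are permuted across the slots vacated by other migrants of the
same sex, metapopulation-wide, so subpopulation sizes and sex ratios are
preserved; a migrant can land back home with probability of order one over
the number of subpopulations (excluding the origin would complicate the
slot accounting for a vanishing effect at the default 20 subpopulations).

Within each subpopulation, drift fixes one or the other male trait;
conformist females, by mating assortatively with the local majority,
generate a *statistical* linkage disequilibrium between C and the locally
common trait — the Fisher runaway's engine — and hitchhike to higher
frequency while diversity lasts. Dispersal among subpopulations that have
fixed *different* traits keeps reintroducing the variation the process
consumes. Hence the central contrast: in one unstructured population male
diversity collapses quickly and C drifts neutrally, while in a structured
metapopulation with modest dispersal ($d$ small relative to $\beta$)
conformity can rise well above its initial frequency.

### Parameters and defaults

| Parameter | Meaning | Default |
|---|---|---|
| `beta` | conformity strength of C females | 2.8 |
| `d` | offspring dispersal fraction per generation | 0.02 |
| `r` | recombination rate between the loci | 0.2 |
| `q0` | initial frequency of C | 0.2 |
| `alpha` | choice error rate of C females | 0 |
| `n_subpop` × `subpop_size` | metapopulation shape | 20 × 50 |
| `generations` | fixed horizon (runs continue past fixation so output stays rectangular) | 500 |

`beta = 2.8`, `d = 0.02`, `q0 = 0.2` and `r = 0.2` are the canonical
parameter set for this model. The metapopulation shape is not part of
that canon; 20 subpopulations of 50 make within-subpopulation fixation
fast enough to watch the runaway at desk scale, and both numbers are
configurable. Where the tests and the acceptance script need many
replicates they use small metapopulations of 20-individual subpopulations
for 300 generations (10 subpopulations for the structured-vs-unstructured
contrast and the 50-generation neutrality check, 20 for the dispersal
sweep, where the metapopulation mean needs the extra precision that more
independent subpopulations provide); at these sizes every reported
contrast is unambiguous.

Two points the verbal model leaves open are implemented as explicit
options:

* **What the female observes.** `perception = "male-frequency"` (default)
  uses the standing frequency of A among the subpopulation's adult males;
  `"mating-observation"` uses the traits of the matings already realised
  this generation locally (females then choose in random order, the first
  falling back to the male frequency). Neither reading is privileged;
  both are implemented and the qualitative results agree.
* **Ploidy.** Individuals are haploid two-locus carriers — the minimal
  reading of "conformist or random-mating females"; diploidy would add
  dominance decisions the model never states.

### Determinism and seeding

Every run is a pure function of its `sim_params`, including `seed`; the
caller's RNG stream is saved and restored. Sweeps derive one seed per
(cell, replicate) by a counter scheme, so any single replicate can be
reproduced in isolation, and `run_sweep()` records it in its output.

```{r sim}
res <- run_simulation(sim_params(n_subpop = 10, subpop_size = 20,
                                 beta = 2.8, d = 0.02, q0 = 0.2, r = 0.2,
                                 generations = 300, seed = 42))
summary(res)[c("final_freq_C", "var_among_subpop_freq_A",
               "n_polymorphic_subpops")]
```

## What the synthetic data do and do not show

The choice-table generator draws binomial adoptions from the exact
logistic (or mixture) rule at fixed design frequencies: it emulates ideal
grouped experiments with independent observers, a known demonstrator
frequency, and no observer heterogeneity. Real datasets add measurement
error in $q$, correlated observers, group-level heterogeneity in $\beta$,
and unbalanced designs — none of which the generator produces. Passing
recovery and calibration tests therefore shows the estimators are correct
*for the model's own data-generating process*, not that the model fits any
particular empirical system. Likewise the simulator is an island-model
idealisation: no overlapping generations, no cost of choosiness, no male
mate limitation, two alleles per locus, and dispersal that ignores
geography. Its tested claims are directional (conformity rises under low
dispersal, stays neutral without structure), not quantitative curve
matches — the published parameter set does not pin down group sizes, so
quantitative trajectories are not reproducible even in principle.

## Known limitations

* The log-odds regression treats groups as independent; repeated measures
  on the same observers need a mixed-model extension that is out of scope.
* Observed-information standard errors from the mixture fit are
  unreliable when $\hat\alpha$ sits on the boundary (the common case
  $\hat\alpha = 0$); the fit flags this rather than correcting it.
* `mating-observation` perception is sequential and therefore slower than
  the vectorised default.
* The simulator's dispersal pools migrant slots per sex across the whole
  metapopulation; with very few subpopulations the self-return probability
  is non-negligible.
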