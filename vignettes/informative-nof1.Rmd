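---
title: "Evaluating informative hypotheses across multiple N-of-1 binomial experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating informative hypotheses across multiple N-of-1 binomial experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nof1bf)
```

## The model and the question

A within-subject experiment exposes each person $i = 1,\dots,P$ to the same
$J$ conditions and records $R$ dichotomous trials per condition, giving
success counts $x^i_j \sim \mathrm{Binomial}(R, \pi^i_j)$, independently over
conditions.  Many substantive theories are *ordinal*: they say which
conditions should have higher success probabilities, not by how much.  Such
theories are written as informative hypotheses
$$H_m^i : R_m \, \boldsymbol\pi^i > 0,$$
where $R_m$ is a $K \times J$ constraint matrix.  A full ordering
$\pi_1 > \pi_2 > \pi_3 > \pi_4$ is the matrix with rows
$(1,-1,0,0)$, $(0,1,-1,0)$, $(0,0,1,-1)$; an "averages" hypothesis
$(\pi_1+\pi_2)/2 > (\pi_3+\pi_4)/2$ is the single row
$(.5,.5,-.5,-.5)$.  Crucially, the analysis is run *per person*: a
hypothesis that holds for the population average need not hold for any
individual, and the package's purpose is to keep those two questions apart.

## Per-person Bayes factors

With a uniform $\mathrm{Beta}(1,1)$ prior per condition, the encompassing
(unconstrained) prior and posterior both factor into $J$ independent Beta
laws; the posterior has parameters $\alpha_1 = x_j + 1$,
$\beta_1 = R - x_j + 1$.  The Bayes factor of $H_m$ against the
unconstrained hypothesis $H_u$ reduces to
$$BF_{mu} = f_m / c_m,$$
where the *complexity* $c_m$ is the prior probability of the constrained
region and the *fit* $f_m$ is its posterior probability.  Three derived
comparisons follow:

* $BF_{mm'} = BF_{mu} / BF_{m'u}$ compares two informative hypotheses;
* $BF_{m\bar m} = (f_m/c_m) / ((1-f_m)/(1-c_m))$ compares $H_m$ with its
  complement ("$H_m$ is not true") and, unlike $BF_{mu}$ (bounded above by
  $1/c_m$), ranges over $(0, \infty)$ — the natural scale for asking whether
  the best hypothesis is also a *good* one;
* a decision rule calls $H_m$ *best* for a person when
  $BF_{mm'} \ge \max(M-1, 2)$ for every rival $m'$, which guarantees
  posterior probability at least .5 for $H_m$ under equal prior weights.
  The threshold is exposed as an argument because it is one reasonable
  convention, not a theorem.

### Monte Carlo estimation instead of MCMC

Because prior and posterior are products of independent Betas, $c_m$ and
$f_m$ are estimated by *direct* independent sampling — an $N \times J$ pool
of `rbeta` draws — rather than MCMC; the sampler is exact, embarrassingly
vectorisable, and every proportion carries the exact binomial standard
error $\sqrt{p(1-p)/N}$, which the package propagates into the Bayes
factors by the delta method.  The default pool size is $N = 10^5$ per
person (standard error below $0.002$ on any proportion); the worked-example
reproductions in the test suite use $10^6$.

All hypotheses of a set are scored against *one shared prior pool* and, per
person, *one shared posterior pool*.  This makes two identities exact in
finite samples rather than approximate: pairwise Bayes factors equal the
ratio of the stored $BF_{mu}$, and $f_m + f_{\bar m} = 1$.

Complexities of complete simple orderings need no sampling at all: under
the exchangeable uniform prior every one of the $J!$ orderings is equally
likely, so $c_m = 1/J!$ exactly.  The package detects this structure and
attaches the analytic value alongside the Monte Carlo estimate; for any
other constraint structure the estimate stands alone.

### Numerical conventions

* **Boundaries.**  Membership is strict on both sides: a draw with any row
  product exactly zero satisfies neither the hypothesis nor its complement.
  The event has probability zero under continuous Betas; complement
  *estimates* are computed as one minus the informative estimate on the
  shared pool, so the (at most measure-zero) boundary is accounted to the
  complement and the two proportions always sum to one.
* **Zero fits.**  A posterior region never hit at pool size $N$ yields
  $f = 0$ and $BF = 0$; the smallest representable non-zero fit is $1/N$.
  No pseudo-count correction is applied — inventing one would smuggle in an
  undeclared prior.  Zero Bayes factors propagate honestly: they annihilate
  the P-BF and gP-BF, and the printed output flags them.
* **Degenerate inputs.**  A complexity estimate of exactly 0 (the region
  was unsamplable at this pool size) is an error, not an infinity.

## Aggregating evidence over persons

For one fixed comparison, the $P$ per-person Bayes factors combine into

$$\text{P-BF} = \prod_i BF^i, \qquad
  \text{gP-BF} = \left(\text{P-BF}\right)^{1/P},$$

the product (support for "the hypothesis holds for *every* person") and its
geometric mean (the Bayes factor expected for a next person, independent of
$P$).  Two rates qualify the gP-BF:

* **Evidence rate (ER)** — the proportion of individual Bayes factors on
  the same side of 1 as the gP-BF: a homogeneity measure;
* **Stability rate (SR)** — the proportion strictly more extreme than the
  gP-BF on its side: values far from .5 flag a gP-BF driven by a minority
  of extreme persons.

Indicator counts are strict: a Bayes factor exactly equal to 1 (or to the
gP-BF) counts for neither side.  When the gP-BF is exactly 1 both rates are
undefined and returned as `NA` with a flag — such cases carry no
directional signal, and picking a side silently would manufacture one.
Comparisons are never mixed: the gP-BF of $m$ versus $u$ says nothing about
$m$ versus its complement, so `aggregate_bf()` aggregates each comparison
tag separately.

**Censored published inputs.**  Published Bayes factor tables sometimes
print "< 0.01".  Such entries are ingested as the bound value with a censor
flag.  The resulting gP-BF is an *upper bound* on the true gP-BF, and its
side of 1 may even differ from the truth; the `gp_override` argument of
`aggregate_bf()` (mirrored by the `gp` argument of `evidence_rate()` /
`stability_rate()`) therefore accepts a published gP-BF as the
side-defining reference, so the exact ER/SR counts can still be reproduced
from a censored table.

## Design analysis: choosing P and R

Before collecting data one wants to know which sample size $P$ and
replication count $R$ let the three summaries detect homogeneity when it is
there — and heterogeneity when it is not.  `run_design()` implements a
two-stage simulation:

1. **Surrogate stage.**  For each generating population and each $R$:
   draw `surrogate_size` parameter vectors $\boldsymbol\pi^i$ from the
   uniform prior truncated to the hypothesis region (`under_h`), to its
   complement (`under_complement`), or to a $\theta$-mixture of the two;
   sample counts $x^i \sim \mathrm{Binomial}(R, \pi^i)$; compute each
   person's Bayes factor (by default versus the complement, the comparison
   that answers "does $H$ hold for this person?").  The resulting pool
   stands in for the infinite population of persons.
2. **Bootstrap stage.**  For each $P$: resample `n_boot` sets of $P$
   Bayes factors with replacement from the surrogate, compute gP-BF, ER and
   SR per set, and report their 2.5/50/97.5 percentiles.  Resamples whose
   gP-BF is exactly 1 leave ER/SR undefined; they are excluded from the
   percentiles and reported as an `undefined_rate`.

Sampling the truncated prior uses an exchangeability shortcut for complete
orderings — sort $J$ iid uniforms into the required order — which is exact
and acceptance-free even where rejection sampling would accept one draw in
$J!$ (at $J = 8$: one in 40320).  Arbitrary constraint regions fall back to
batched rejection sampling with an adaptive batch size and a configurable
candidate budget; exhausting the budget is an error that reports the
estimated acceptance rate rather than silently returning a short sample.

Median ER at least .9 and median SR within .1 of .5 are the default
desiderata flagged in the result (`er_target`, `sr_margin`); no gP-BF
threshold is imposed, since how much average evidence is "enough" is a
substantive judgement.

### Reference and desk-scale sizes

The reference configuration is a surrogate of 10000 persons and 1000
bootstrap sets per cell.  Those sizes are set as the defaults, but every
size is configurable, and the package's own test suite exercises a reduced
configuration — surrogate 2000, 200 bootstrap sets, per-person pools of
$10^5$, a single cell $R = 21$, $P = 30$ at $J = 8$ — which reproduces the
qualitative findings: under the hypothesis the median ER reaches .9 and the
median gP-BF versus the complement is far above 10; under the complement
the median gP-BF collapses below 1; under a $\theta = .5$ mixture the
median ER settles near .5.  The bundled acceptance script runs a further
reduced configuration (surrogate 500, pools of $10^4$).

One behaviour of the scaled-down runs deserves a note: under the complement
(and for the complement half of a mixture), posterior mass on an eight-way
ordering is often below the pool resolution $1/N$, so those persons' Bayes
factors are exactly 0, making bootstrap gP-BFs exactly 0.  The direction of
the conclusion is unaffected (gP-BF < 1, ER counts the zeros correctly),
but the mixture-population SR then counts "more extreme than 0" and returns
0 rather than hovering below .5 as it would with unbounded-resolution
Bayes factors.  Larger per-person pools shrink the set of exact zeros.

## What the simulations do and do not show

The generating populations of the design analysis are *prior-truncated*
populations: persons under $H$ are uniform over the constrained region,
not clustered at substantively plausible effect sizes.  This matches the
method's own encompassing-prior logic and needs no extra assumptions, but
it means the design curves average over both near-boundary persons (hard to
detect) and well-separated ones (easy); a researcher with a sharper prior
guess about effect sizes should read the medians as averages over that
whole region.  Real data can also violate the model itself — trials within
a condition may be dependent, $R$ may differ across conditions or persons,
and success probabilities may drift over trials; none of these are
represented, and unequal $R$ is deliberately unsupported.  Equality ("about
equal") and range constraints are out of scope, as are hypotheses about the
population-average parameter vector: the package is about the collection of
individual within-person populations.

## Parameter summary

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `n_draws` | `evaluate_hypotheses()` | $10^5$ | pool size per person; MC se $\le \tfrac{1}{2\sqrt{N}}$ |
| `threshold` | `evaluate_hypotheses()` | $\max(M-1,2)$ | best-hypothesis decision rule |
| `surrogate_size` | `design_config()` | 10000 | surrogate persons per (population, R) cell |
| `n_boot` | `design_config()` | 1000 | bootstrap sets per (population, R, P) cell |
| `theta` | `design_config()` | .5 | mixture proportion adhering to $H$ |
| `er_target` | `design_config()` | .9 | desired median evidence rate |
| `sr_margin` | `design_config()` | .1 | acceptable median SR distance from .5 |
| `seed` | everywhere | none | root seed; child streams are derived per person/cell |

## A compact end-to-end example

```{r example, eval = FALSE}
lay <- condition_layout(c("c1", "c2", "c3", "c4"), replications = 7)
hs <- hypothesis_set(
  H1 = "c1 > c2 > c3 > c4",
  H2 = "(c1 + c2)/2 > (c3 + c4)/2",
  layout = lay
)
ev <- evaluate_hypotheses(nof1_fixture("table1"), hs,
                          n_draws = 1e5, seed = 1)
aggregate_bf(bf_long(ev, families = "unconstrained"))
autoplot(ev)
```
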