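# nof1bf

Bayesian evaluation of **informative (inequality-constrained) hypotheses**
in multiple **N-of-1 within-subject binomial experiments**, with
aggregation of per-person evidence and a simulation-based design analysis.

## Who this is for

Researchers running within-subject experiments where each person completes
`R` dichotomous trials in each of `J` conditions (e.g. memory tasks under
crossed reward/interference manipulations), whose theories are *ordinal* —
"condition 1 beats condition 2 beats condition 3" — and who want to know,
person by person, which theory the data support, and then whether the
*population of persons* is homogeneous in that support.  A hypothesis that
holds on average can fail for most individuals; this package keeps the two
levels of inference separate.

## The statistics in brief

An informative hypothesis constrains the condition success probabilities
`π` of one person by strict linear inequalities, `H_m: R_m π > 0`.  With a
uniform Beta(1,1) prior per condition the prior and posterior factor into
independent Betas, and the Bayes factor of `H_m` against the unconstrained
hypothesis `H_u` is the fit/complexity ratio

    BF_mu = f_m / c_m

with `c_m` the prior and `f_m` the posterior probability of the constrained
region, both estimated by direct Monte Carlo on shared draw pools (for a
complete ordering of all `J` conditions, `c_m = 1/J!` exactly).  Derived
from it: pairwise `BF_mm' = BF_mu / BF_m'u`, and the complement Bayes
factor `(f/c) / ((1−f)/(1−c))` — "is `H_m` true or not?".  Across `P`
persons, per comparison:

* `P-BF` — product of individual Bayes factors;
* `gP-BF` — its P-th root, the average evidence per person;
* `ER` (evidence rate) — proportion of persons on the gP-BF's side of 1;
* `SR` (stability rate) — proportion strictly more extreme than the gP-BF.

A two-stage design analysis (truncated-prior surrogate population +
bootstrap) shows which `(P, R)` make these summaries behave as desired.

## Worked example

Three hypothetical persons (`J = 4`, `R = 7`) against a full ordering H1
and an averages hypothesis H2:

```r
library(nof1bf)

counts <- nof1_fixture("table1")     # person_id, c1..c4 success counts
hs     <- nof1_fixture("table1_hypotheses")
ev     <- evaluate_hypotheses(counts, hs, n_draws = 1e5, seed = 1)
ev
#> # Per-person evaluation of 2 informative hypotheses (N = 1e+05 draws per pool)
#> # A tibble: 6 × 9
#>   person hypothesis complexity complexity_se   fit fit_se  bf_u bf_u_se   bf_c
#>    <dbl> <chr>           <dbl>         <dbl> <dbl>  <dbl> <dbl>   <dbl>  <dbl>
#> 1      1 H1               0.04             0  0.55      0 13.4     0.21  28.7
#> 2      1 H2               0.5              0  1         0  1.99    0.01 265.
#> 3      2 H1               0.04             0  0.06      0  1.38    0.03   1.4
#> 4      2 H2               0.5              0  0.89      0  1.79    0.01   8.49
#> 5      3 H1               0.04             0  0.01      0  0.24    0.01   0.23
#> 6      3 H2               0.5              0  0.5       0  1       0      1.01
#> # Decision rule (threshold 2): 2 of 3 person(s) with a best hypothesis (H1, H2)
```

Reading person 1: the full ordering's complexity is 1/24 ≈ .04 and its
posterior fit .55, so the data multiplied its support 13-fold against the
unconstrained model and 29-fold against its own negation — a best *and*
good hypothesis.  Person 3's data contradict the ordering (`bf_u = 0.24`).
Aggregating the `BF_mu` column over the three persons:

```r
aggregate_bf(bf_long(ev, families = "unconstrained"))
#> # P-population aggregation of per-person Bayes factors
#> # A tibble: 2 × 9
#>   comparison     n  p_bf gp_bf    er    sr any_zero censored undefined
#>   <chr>      <int> <dbl> <dbl> <dbl> <dbl> <lgl>    <lgl>    <lgl>
#> 1 H1_vs_u        3  4.47  1.65  0.67  0.33 FALSE    FALSE    FALSE
#> 2 H2_vs_u        3  3.57  1.53  1     0.67 FALSE    FALSE    FALSE
```

The average evidence per person (gP-BF) is modest for both hypotheses; the
evidence rate shows H2 is supported by every person but H1 only by two of
three.  `autoplot(ev)`, `autoplot(aggregate_bf(...))` and
`autoplot(run_design(...))` draw the standard displays; `tidy()` and
`glance()` return broom-style tibbles.

Design analysis ahead of a study (which `P`, which `R`?):

```r
lay <- condition_layout(paste0("c", 1:8), replications = 7)
h1  <- parse_hypothesis(paste(paste0("c", 1:8), collapse = " > "), lay)
cfg <- design_config(h1, r_grid = c(7, 14, 21), p_grid = c(10, 20, 30),
                     surrogate_size = 2000, n_boot = 200, seed = 1)
res <- run_design(cfg)   # long tibble of 2.5/50/97.5 percentiles
autoplot(res)
```

A thin command-line front end wraps the same functions
(`exec/nof1bf.R evaluate | aggregate | design | fixture`).

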