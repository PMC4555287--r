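---
title: "Model averaging over DAG-derived confounder adjustment sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model averaging over DAG-derived confounder adjustment sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A causal diagram (DAG) drawn before data analysis usually identifies not one
but several sufficient confounder adjustment sets: covariate sets that block
every backdoor path from the exposure to the outcome and contain no
descendant of the exposure. In theory, adjusting for any of them yields an
unbiased estimate of the same causal effect. In practice the estimates
differ, and picking one model after seeing the results invites "wish bias"
— the tendency to report the model that best supports a preferred
conclusion. causalMA instead fits every candidate model the diagram
supports and averages them, so the reported estimate carries the
between-model uncertainty rather than hiding it.

```{r}
library(causalMA)
dag <- causal_dag("A -> E; A -> B; B -> D; E -> D; exposure: E; outcome: D")
adjustment_sets(dag, minimal_only = FALSE)
```

This two-confounder diagram is the canonical illustration: `{A}`, `{B}` and
`{A, B}` are all sufficient, `{A}` and `{B}` are minimally sufficient, and
nothing in the graph privileges one over another.

## Graphical machinery

Sufficiency is decided by the backdoor criterion, implemented with
d-separation. `d_separated()` uses the reachability ("Bayes-ball")
formulation — a breadth-first search over (node, direction) states — which
costs linear time per query; a collider passes the ball back to its parents
exactly when it or one of its descendants is conditioned on. The test suite
checks this implementation against a deliberately naive oracle that
enumerates every simple path and applies the chain/fork/collider rules
triple by triple. The oracle comparison runs exhaustively over all 543
labelled DAGs on 4 nodes (every node pair crossed with every conditioning
subset) and over 200 random DAGs on up to 8 nodes; exhaustive coverage at
larger orders adds nothing qualitatively while the number of labelled DAGs
grows super-exponentially, so 4 nodes exhaustive plus random 8-node graphs
is the coverage this package commits to.

`adjustment_sets()` enumerates subsets of the *eligible* covariates (all
nodes except exposure, outcome, and exposure descendants), orders output by
set size then lexicographically so set numbering is reproducible, and
refuses more than 20 eligible covariates by default — subset search is
exponential, and real diagrams in this setting have far fewer relevant
nodes.

## Per-model fitting

Each adjustment set is fit as a log-link binomial GLM of the binary outcome
on exposure indicators plus the set's covariates, on the complete cases of
the involved columns only. The log link returns risk ratios, which —
unlike odds ratios — are collapsible: marginal and conditional effects
coincide in the absence of confounding, so estimates from different
sufficient sets target the same quantity and can be meaningfully averaged.
`check_collapsible()` enforces this at the interface: odds- and
hazard-ratio requests draw a prominent warning and require an explicit
override.

Log-binomial likelihoods are notoriously fragile near the `p = 1` boundary.
The fitter starts at the marginal log-risk intercept with zero slopes and,
when the fit fails to converge (or produces aliased coefficients), refits
as a log-link Poisson regression with robust sandwich standard errors — the
"modified Poisson" risk-ratio estimator — recording `family_used` so every
report discloses the fallback. Convergence uses `glm`'s relative deviance
tolerance of `1e-8` with up to 100 iterations; both are arguments of
`fit_rr_model()`.

Continuous covariates enter untransformed; categorical covariates are
reference-coded with the lowest-coded level as reference. Missing data are
handled by complete-case analysis throughout, which is valid under the
missing-completely-at-random assumption the simulator (below) implements.

## The three averaging schemes

All pooling happens on the log-RR scale; ratios are exponentiated at the
end. With per-model log risk ratios $\hat\theta_i$, standard errors $s_i$,
and complete-case counts $n_i$:

**Information-criterion weighting.** Weights follow the Burnham–Anderson
construction $w_i = \exp(-\Delta_i/2)/\sum_j \exp(-\Delta_j/2)$ with
$\Delta_i = \mathrm{AIC}_i - \min_j \mathrm{AIC}_j$ (BIC may be substituted).
The average is $\bar\theta = \sum_i w_i \hat\theta_i$ and its
*unconditional* standard error adds the between-model spread to each
model's own variance:
$\bar s = \sum_i w_i \sqrt{s_i^2 + (\hat\theta_i - \bar\theta)^2}$.
Information criteria are only comparable between models fit to the same
observations, so `dag_average()` refits all candidates on the rows complete
for the union of all sets' covariates (`common_complete_rows()`) before
weighting. That common subset is typically smaller than any single model's
complete-case count — the price of comparability.

**Inverse-variance weighting.** The point estimate is the classical
precision-weighted mean
$\bar\theta = \sum_i (\hat\theta_i/s_i^2) / \sum_i (1/s_i^2)$, each model
keeping its own complete cases. The pooled standard error is the
sample-size-weighted arithmetic mean $\bar s = \sum_i n_i s_i / \sum_i n_i$
rather than the fixed-effect meta-analytic $\sqrt{1/\sum_i s_i^{-2}}$: the
candidate models are fit to overlapping subsets of one cohort, not to
independent samples, so the meta-analytic formula would be severely
anti-conservative. The n-weighted mean keeps the pooled interval on the
scale of a single model's interval while letting better-supported (larger
complete-case) models dominate.

**Bootstrap pooling.** Each of `B` replicates (default 1000) resamples the
*full* dataset with replacement — incomplete rows included — and refits
every model to its own complete cases within the replicate. All finite log
RRs are pooled across the `B × M` replicate-by-model matrix; the summary
reports the exponentiated mean, median, and 2.5th/97.5th percentiles
(linear interpolation between order statistics, quantile type 7 — pinned
because percentile definitions differ across software). Replicate fits
that fail are dropped and counted, never imputed; the count is exposed in
the `bootstrap_pool` object so silent attrition is impossible. Ratio-scale
pools are typically right-skewed, which is why the pooled median sits
slightly below the mean.

The 95% intervals use `z = qnorm(0.975)` (1.959964…) internally; rounding
to 2 decimals happens only in reports.

A worked illustration on published per-model summaries ships with the
package; the averaging-only entry point rebuilds log-scale standard errors
from printed CIs via `se_from_ci()`:

```{r}
avg <- average_summaries(
  system.file("extdata", "bmi_cesarean_aic.csv", package = "causalMA"),
  methods = "ic")
avg
```

One caution on such reconstructions: inputs printed at 2 decimal places
carry rounding error of their own, so CI bounds rebuilt from them can move
by ±0.01 relative to the originally computed values.

## The synthetic-cohort generator

Because the original individual-level data behind the worked example are
not distributable, validation rests on structural models with *known*
effects. `structural_model()` couples a DAG with one mechanism per node
(Bernoulli with logit or log link, multinomial logit, Gaussian linear),
samples in topological order, and injects missing-completely-at-random
masking per column. The outcome mechanism is constrained to the log link
so that its exposure coefficients are exact conditional — and, by
collapsibility, marginal — log risk ratios; `true_marginal_rr()` verifies
this by simulating the interventional contrast directly (forcing the
exposure and re-drawing its descendants), which doubles as a check that a
preset's nominal effect really is its causal effect.

Two presets define the package's standing test conditions:

* `fig1-confounding`: the two-confounder diagram above with a binary
  exposure, true causal RR 2.0, outcome baseline risk 6%, and MCAR rates
  of 5% (A) and 8% (B). The crude (unadjusted) estimate is biased upward
  by about 0.05 on the log scale — enough that the test suite can
  demonstrate the confounding is real — while every sufficient set
  recovers RR 2.0.
* `pin-shaped`: a pregnancy-cohort-shaped model with a 3-level exposure
  (BMI class, marginal proportions ≈ 0.49/0.19/0.33), a binary delivery
  outcome with ≈ 23% prevalence, seven mixed-type covariates and
  per-column MCAR rates of 2–8%. Two substitutable confounder chains
  (hypertension/pre-eclampsia and height/weight-gain) produce four
  minimally sufficient sets of five covariates each, so the averaging
  machinery is exercised with the same multiplicity pattern as the
  motivating application. True RRs are 1.4 (overweight) and 1.8 (obese).

What the generator does *not* emulate: informative missingness (only MCAR,
because complete-case validity is an assumption of the procedure, not a
claim), measurement error, selection into the cohort, or effect-measure
modification. Passing tests therefore demonstrate correctness of the
machinery under the procedure's own assumptions, not robustness to their
violation.

## Problem sizes and numerical choices

Test-suite simulations are sized to make Monte-Carlo error decisively
smaller than the effects being checked while keeping the default run fast:
single-cohort parameter recovery at n = 20,000; repeated-cohort bias checks
at 150 replicates of n = 2,000 (the crude-estimate bias of ≈ 0.05 log
units needs roughly a hundred replicates to clear a 5-standard-error
detection bound); bootstrap checks at B = 50–200. Degenerate inputs are
rejected rather than patched: constant outcomes, empty complete-case sets,
and non-positive CI bounds raise errors naming the offending condition, and
a structural model whose log-link risks exceed 1 for more than 1% of
subjects is treated as misparameterized rather than silently clipped.

## Limitations

* Identification is backdoor-only: no latent-variable or selection-node
  semantics, no front-door or instrumental-variable adjustment.
* Subset enumeration is exponential; the 20-covariate ceiling is a guard,
  not a solved scaling problem.
* The averaged interval never reflects uncertainty about the *diagram*
  itself — a wrong DAG invalidates all candidate models at once.
* Bayesian model averaging, shrinkage and stacking are out of scope.
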