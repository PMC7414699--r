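---
title: "Path-specific effect statistics for two-group network comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-specific effect statistics for two-group network comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(psepath)
```

## The problem

Systems-epidemiology studies represent a disease process as a causal
directed acyclic graph (DAG) over measured variables — risk factors,
intermediate phenotypes, molecular markers, an outcome — and ask which
*directed paths* through the network behave differently between two
conditions (cases versus controls, exposed versus unexposed, long versus
short survivors).  A total exposure–outcome association is blind to this
question: effect can redistribute across parallel paths, or change on one
path while the overall association barely moves.  `psepath` implements a
path-specific effect (PSE) statistic that targets one directed path at a
time and tests whether the effect transmitted along it differs between the
two groups.

## The estimand and the estimator

For a path $X_1 \to X_2 \to \cdots \to X_K \to Y$, the effect of each edge
$A \to B$ is the average causal effect (ACE) of $A$ on $B$,
$E[B \mid do(A=x')] - E[B \mid do(A=x'')]$, identified from observational
data by back-door adjustment for the *parents of the child* other than $A$
itself: by the local Markov property a node is screened from every
back-door route by its remaining parents, so no search over adjustment sets
is needed.  The path effect is the product of the per-edge ACEs, scaled by
$\prod_{i=2}^{K}(x_i' - x_i'')$ for interior mediators estimated on a level
contrast (for the slope convention of continuous mediators and the default
$(1,0)$ contrast of binary mediators the divisor is 1).

Per-edge estimators by declared child kind:

* **continuous** — the coefficient of $A$ in the least-squares fit of $B$
  on $A$ and the covariates (the derivative $\partial E(B\mid A,C)/\partial
  A$, a unit-change effect);
* **binary** — the standardized risk difference
  $\sum_c [\hat P(B{=}1 \mid A{=}x', c) - \hat P(B{=}1 \mid A{=}x'', c)]
  \hat P(c)$;
* **ordered discrete** — the same standardization through the
  CDF-differencing form, which reduces exactly to the binary case at two
  levels.

For binary children two standardization routes are available.  The
nonparametric **stratified sum** is the saturated-model estimator of the
estimand and is the default whenever the covariates are discrete and the
stratum table is small relative to $n$ (the fully discrete simulation
networks here always qualify); **model-based** standardization fits a
main-effects logistic regression and averages predicted probabilities over
the empirical covariate rows, and is the fallback when strata are many or
covariates continuous.  The two agree exactly when the model is saturated
and agree asymptotically when the main-effects model is correctly
specified; with continuous confounders inside a discrete path only the
model route is available, and its no-interaction form is a known
limitation.

Network simplification (`simplify_dag()`) removes every variable with no
directed route into a path node or an adjustment-set node.  Such variables
cannot open a back-door route into any on-path edge, so removal provably
leaves every per-edge estimand unchanged — it is a readability and
bookkeeping device, not an approximation.  "No causal effect on" is
interpreted structurally, as graph reachability.

## The two-group statistic

Within each group $g$ the standardized path effect is
$\mathrm{PSE}_g = \widehat{\mathrm{ACE}}_g / S_{\widehat{\mathrm{ACE}}_g}$,
with $S$ a nonparametric bootstrap standard error of the path-effect
product over resamples of that group's rows (the PSE definition does not pin
down the SE estimator; the bootstrap is the natural nonparametric choice
and is pinned against a closed form on a two-sample-mean reduction
in the tests).  The hypotheses are $H_0: \mathrm{PSE}_1 = \mathrm{PSE}_0$
against a two-sided alternative.

### Permutation test

Group labels are reassigned uniformly without replacement (group sizes
fixed), the statistic is recomputed per reassignment, and the two-sided
p-value is `(1 + #{|T_b| >= |T_obs|}) / (B + 1)` — the add-one convention
avoids $p = 0$ and keeps the test valid at any $B$.

The default permutation statistic is the **raw difference of path-effect
products** $\widehat{\mathrm{ACE}}_1 - \widehat{\mathrm{ACE}}_0$.  This was
a deliberate design decision, made after measurement.  The alternative —
differencing the per-group *standardized* effects — looks natural, but the
standardized effect is a signal-to-noise ratio: once the path effect is
individually well-resolved in *both* groups, both ratios saturate and their
difference shrinks even as the underlying effects diverge.  On the binary
reference network we measured its power *decreasing* from 1.00 to 0.41 as
the base effect grows with the group difference held fixed, the opposite of
the expected monotone trend, while the raw difference is
monotone.  Since a permutation test is exact for any statistic under
exchangeability, studentization buys no validity here; it only costs power
and an inner bootstrap per permutation.  `statistic = "standardized"`
retains the other convention.

### Bootstrap confidence-interval tests

Rows are resampled with replacement within each group independently
(stratified resampling keeps the group sizes fixed; unstratified resampling
would perturb them and conflate group-size noise with effect differences).
Each draw of $\theta^* = \mathrm{PSE}_1^* - \mathrm{PSE}_0^*$ standardizes
the resampled products by the *observed* group SEs; re-estimating the SE
inside every draw (a double bootstrap) is available as
`draw_se = "resample"`.  Four intervals are built on the draws; $H_0$ is
rejected when the interval excludes zero.

A naming caveat is deliberate: the labels follow the formula printed
under each name in the reference methodology this harness reproduces,
which swaps the conventional "basic"/"percentile" names.  Here `basic` is the plain
order-statistic interval
$(\theta^*_{[(B+1)\alpha/2]}, \theta^*_{[(B+1)(1-\alpha/2)]})$ and
`percentile` is the reflected interval $(2\hat\theta -
\theta^*_{[(B+1)(1-\alpha/2)]}, 2\hat\theta - \theta^*_{[(B+1)\alpha/2]})$.
Order-statistic indices use $\lceil (B+1)q \rceil$ clipped to $[1, B]$.
The BCa interval uses the median-bias constant
$\hat z_0 = \Phi^{-1}(\#\{\theta^* < \hat\theta\}/B)$ and the jackknife
skewness acceleration; the jackknife perturbs the path-effect products with
the SE denominators frozen at their observed values (a full nested
jackknife would re-bootstrap the SE at every leave-one-out point at
prohibitive cost for no practical gain — the BCa correction is already a
second-order refinement of a deeply conservative interval here).  On fully
discrete paths identical rows are collapsed, so the jackknife costs at most
one evaluation per occupied contingency cell.

These bootstrap tests are *severely conservative* for long near-null paths,
and reproducing that miscalibration is part of the package's validation.
The mechanism: by construction the spread of the standardized draws is
$\approx \sqrt 2$, but for a product of several near-null edge effects the
sampling spread of the observed statistic is far smaller, so the intervals
are systematically too wide and almost never exclude zero.  At $n = 1000$
per group on the binary reference network we measure type-I error 0.000 for
all four intervals against 0.05–0.07 for the permutation test.  The
permutation test is the recommended default.

## The estimation engines

Resampling dominates the cost, so two engines compute the path product
under resampling:

* **cell engine** — when every involved variable (path nodes plus
  adjustment covariates) is discrete, a group's sample reduces to a joint
  contingency table over at most `r psepath:::MAX_CELLS` cells.  A
  bootstrap resample of rows is *exactly* a multinomial draw over cells,
  and a permutation of group labels is a random split of the pooled
  cell-id vector, so resampling vectorises into `rmultinom()` plus
  `rowsum()` collapses with no model refits.  This is an exact
  reformulation, not an approximation, and the tests pin its output to the
  standalone estimators to 1e-12.
* **generic engine** — row-index resampling with per-resample
  least-squares (continuous children) or logistic (binary children) fits,
  for continuous and mixed paths.

Degenerate resamples (an empty stratum at a contrast level, a
rank-deficient design) are skipped and counted; more than 10% skips is an
error rather than a silently noisier answer.

## The synthetic-data generators

`scenario()` fixes a generative law per group: binary nodes are drawn in
topological order from logistic models $\mathrm{logit}\,P(\text{child}=1
\mid \text{parents}) = \alpha_0 + \sum \beta\,\text{parent}$, continuous
nodes from linear models with Gaussian noise.  The two groups share a
graph and differ only on the declared differential edges
($\delta = \beta_1 - \beta_0$ per edge).

Constants the reference designs leave unstated are fixed once at
symmetric, non-degenerate values and not revisited: all intercepts
$\alpha_0 = 0$, binary root prevalence $0.5$, continuous roots standard
normal, noise SD 1, and every unspecified edge coefficient $0.5$ in both
groups.  Two further under-determined choices: in the $\delta$-sweep
designs (the three-edge grids) the fourth on-path edge `vi->inf` stays
non-differential at $0.5$, and the parent/child sensitivity sweeps keep the
target path at its $\delta = 1$ configuration ($0.5$ vs $1.5$), the only
base consistent with the sweeps' reference power levels.

What the generators emulate — and what they do not: faithful per-node
conditional laws, group-specific edge strengths, and exact Markov structure
on a known graph.  Real data violate most of this: the graph is partly
wrong or incomplete, effects are non-linear with interactions, confounders
are unmeasured, and variables are measured with error.  Passing the
simulation checks therefore validates the *statistical machinery* (type-I
control, monotone power, robustness to off-path effects), not the causal
interpretation on any particular real network, which stands or falls with
the correctness of the assumed DAG.

Because absolute power levels depend on the unstated constants above, only
trends and contrasts are comparable across implementations of these
designs; the absolute rejection rates printed by `table_experiment()` are
internally consistent but tied to this package's constants.

## Monte-Carlo harness and problem sizes

`run_mc()` derives one child seed per replication from the root seed, so
results are independent of execution order and reproducible end-to-end;
within a replication the permutation, bootstrap and SE streams are derived
seeds as well.  `table_experiment()` instantiates the reference grids
(sample-size sweeps for the null designs, effect-size and $\delta$ sweeps,
parent/child sensitivity sweeps) and runs every cell.

Default sizes in this package's own validation runs are chosen for a
single-CPU desk machine: 100–200 replications per cell, $B = 99$–$199$
permutations, inner bootstrap 50–100 — a rejection rate then carries a
binomial Monte-Carlo SE of $\sqrt{r(1-r)/\mathrm{reps}}$ (about 0.02 at
$r = 0.05$, reps = 100), which is the resolution at which the validation
asserts its checks.  The full-scale profile (1000 replications,
$B = 999$) is `run_simulation(..., fast = FALSE)`.

## Numerical choices and degenerate inputs

* Deterministic orderings everywhere: nodes lexicographic, topological
  order with a lexicographic frontier, paths shortest-first then
  lexicographic — outputs are byte-stable at a fixed seed.
* Missing values error by default; complete-case filtering is opt-in and
  reports the dropped count.
* Collinear designs error and name the offending columns; a constant child
  yields a zero slope rather than an error.
* An inestimable *observed* statistic is an error; inestimable resamples
  are skipped and counted against the 10% ceiling.
* `x' = x''` contrasts give a zero effect by definition; a zero mediator
  contrast in the path divisor is an error.
* Bootstrap SE of exactly zero (a deterministic path) makes the
  standardized effect infinite with its sign; the raw statistic is
  unaffected.

## Known limitations

* Adjustment models are main-effects only; exposure–covariate interactions
  within an edge are not modelled.
* The causal reading of a multi-edge product with discrete mediators
  additionally requires the stratum-constancy condition (the per-level
  outcome contrasts not varying with the covariates); the package computes
  the product regardless and leaves that condition to the analyst — no test
  of it is provided.
* Identification assumes no unmeasured confounding given each child's
  parents; hidden-variable identification is out of scope.
* The permutation test assumes exchangeable rows under $H_0$; covariate
  imbalance between groups that is not part of the network is not
  addressed.

## A worked example

```{r example}
g <- three_path_network()
enumerate_paths(g, "X1", "Y")

scn <- continuous_scenario(delta = 1.5, n_per_group = 300)
gd <- generate_grouped(scn, seed = 7)

res <- run_analysis(g, gd$data, group = "group", source = "X1", sink = "Y",
                    B = 199, seed = 42, B_se = 100)
res[, c("path", "pse1", "pse0", "diff", "p_value", "reject")]
```

The differential path `X1 -> X2 -> Y` carries the planted group difference;
the other two paths are null and should reject only at the nominal rate.
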