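---
title: "Classifying and simulating selection processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and simulating selection processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selproc)
```

## The problem

A *selection process* is anything that splits a population or cohort
non-randomly — with respect to exposure, health status, membership or
eligibility. Such processes are ubiquitous: every arrow in a causal
diagram that ends in an exposure node selects who becomes, stays or stops
being exposed, and events like disease onset, death or study enrolment
select who remains in the population at all. Their consequences range
from classical confounding through collider stratification bias to
depletion of susceptibles, and must be judged case by case.

`selproc` makes these processes concrete objects. It represents them on
time-indexed causal diagrams, classifies each one on three dimensions,
and turns any diagram into a generative binary structural causal model so
that the resulting distortions of risk-ratio estimates can be computed
exactly rather than argued about.

## The diagram model

A diagram is a set of binary variables placed in discrete time windows
(`E1` = exposure in window 1) with forward-in-time arrows. Each node
carries a role — `exposure`, `outcome`, `covariate`, `unknown_cause`,
`selection`, `side_effect` — and two flags: `conditioned` marks a
"boxed" node the population or the study conditions on (conditioning by
nature or by design), and `study_specific` marks processes that exist
only because of the study. Time indices are ordinal labels, not
durations; arrows may skip windows, since real diagrams routinely draw
e.g. a baseline covariate directly into a late outcome.

Validation is total: every specification either yields a graph
satisfying all invariants or a classed error. Two deliberate
permissions are worth noting:

* **Same-window arrows** are allowed with a warning. Simultaneous
  processes are conventionally drawn vertically aligned; the index-event
  template needs an arrow from exposure to a selection event in the same
  entry window, and rejecting it outright would exclude that structure.
* **Conditioned values.** A boxed node is held at 1 by default
  ("selected", "survived"). Depletion of susceptibles conditions an
  early outcome at 0 (the event-free), so nodes accept an explicit
  `conditioned_value`. Conditioning is restricted to selection nodes and
  outcome nodes; other role/flag combinations are rejected as
  structurally meaningless.

## The three-dimensional classification

`identify_processes()` finds one process per arrow-receiving exposure
node and per boxed node; `classify()` places it in a cell `L.M.T`:

* **Level** (1 population, 2 study-specific) is read from the target's
  `study_specific` flag — it has no structural signature, being a fact
  about why the process exists.
* **Mechanism** (1 in exposure, 2 in population composition) follows
  from the target: arrows into exposure change who is exposed without
  moving the population boundary; a boxed node changes the composition
  of the population itself.
* **Timing** (1 at exposure entry, 2 during exposure, 3 post-outcome)
  uses the precedence post-outcome > during-exposure > entry. A process
  is post-outcome when a direct origin is an outcome node at an earlier
  window (the reversed-causality and Berkson structures both use direct
  arrows from the earlier outcome; outcome *ancestry* alone does not
  trigger it). It is during-exposure when the graph holds an exposure
  node strictly earlier than the target — the process then acts on an
  already-exposed population. Otherwise it occurs at exposure entry.

Two derived annotations complete the picture. A process is
**multifactorial** when at least two distinct origin variables remain
after discounting persistence arrows (`E0 -> E1`), which carry exposure
history rather than an external selection source — otherwise every
continuation process would count as multifactorial. And
`mediated_by_side_effect` flags origins that descend from earlier
exposure, the structure in which an adverse effect of exposure drives
its own termination.

Canonical labels (healthy worker hire effect, Berkson's fallacy, …) are
attached only by structural match against the builtin registry, never
inferred from arbitrary graphs: a label is a name the literature gives a
pattern, not a property derivable from edges alone. For a conditioned
node in a graph with no exposure at all, timing defaults to
at-exposure-entry with a warning — a degenerate input with no meaningful
timing reference.

```{r classify}
framework_report(make_scenario("fig3d")$model$graph)
```

## The generative engine

Every node is Bernoulli given its parents, so a model is the diagram
plus one conditional table per node plus a cohort size N. All inference
is by exact enumeration of the `2^k` configurations (capped at k = 20
with a clear error; every builtin scenario has k ≤ 4), which keeps the
acceptance surface free of sampling noise: conditioning by nature is
renormalized restriction of the joint, expected cohorts are `N * mass`
and are kept real-valued (rounding happens only at presentation).

`sample_cohort()` provides finite-cohort realizations by ancestral
sampling in topological order, using R's default Mersenne-Twister
generator with a caller-supplied seed; identical seeds give identical
cohorts across platforms. Sampled cohorts keep filtered-out individuals
with an `in_population` flag after `apply_selection()`, so pre-selection
truths remain computable next to post-selection analyses; expected-mode
cohorts simply drop the filtered rows.

## Estimators

All estimators work from configuration counts, never from model
parameters, so the same code path serves exact expected cohorts and
sampled ones. Available are risks, crude and stratum-specific risk
ratios, the Mantel–Haenszel summary
(Σ aᵢn₀ᵢ/Tᵢ ÷ Σ cᵢn₁ᵢ/Tᵢ), standardized risk ratios under total /
exposed / unexposed stratum weights, cross-product odds ratios (the lens
for induced collider associations), and IPW risk ratios. Choices made
where the design was open:

* **Zero cells** make an estimate *undefined* (carried as `NA` with a
  status flag) rather than an exception, and no continuity correction is
  applied — corrections would silently change the exact reproductions.
* **Propensities are saturated** empirical frequencies per covariate
  pattern, avoiding an arbitrary parametric choice; with the optional
  `weight_source = "true_model"` the exact model-implied propensity is
  used instead, which may include unknown causes no analyst could
  observe. On an expected cohort the two coincide when all covariates
  are supplied, and full-covariate IPW equals standardization to the
  total population (asserted to 1e-10 in the tests).
* **Display convention**: risks print as whole percent and risk ratios
  to two decimals; stored values are never rounded.
* No confidence intervals are computed by default — the package's
  expected-cohort results are exact, and interval machinery would
  suggest sampling uncertainty where there is none.

## The worked multifactorial-selection cohort

The `table1` scenario is the one externally parameterized model: C and U
independent with P = 0.5; P(E=1|C,U) = 0.10/0.30/0.20/0.50; and
P(D=1|E,C,U) = 0.10 · 2^E · (1.5(1−U) + 4U)^C, N = 4000 (the value
forced by the cohort's printed cell counts of 1000 per C×U stratum).
The risk ratio of E on D is exactly 2.0 in every C×U stratum, while U
modifies the C effect; because exposed and unexposed with the same C
differ in U, every C-only summary is biased:

```{r table1}
print(bias_report(make_scenario("table1")))
```

One quantity this cohort prints cannot be reproduced by any standard
formula: its overall totals row reports a C-adjusted summary of 2.32,
while the crude ratio is ≈ 3.05, the Mantel–Haenszel C-adjusted ratio
≈ 2.34 and C-only IPW ≈ 2.29. The adjustment method behind 2.32 is not
stated; the package reports all standard C-adjusted summaries and leaves
the discrepancy documented rather than matched.

## Scenario registry and its defaults

One scenario exists per fundamental structure: unifactorial and
multifactorial selection, in exposure and in population composition, at
entry (`fig2a`–`fig2d`), during exposure (`fig3a`–`fig3d`) and
post-outcome (`fig4a`–`fig4b`), plus phenomenon aliases
(`healthy_worker_hire`, `berkson`, `depletion`, …). Apart from `table1`,
no external source supplies probabilities, so each scenario's defaults
are this package's own illustrative constants: chosen once in
[0.05, 0.95], documented in the registry source, and fixed by the
requirement that the scenario's qualitative bias signature — e.g.
"OR(E,U|S=1) < 1", "crude RR among survivors < within-stratum RR" —
holds under exact enumeration. They are teaching constants, not
estimates of any real population.

Two modelling conventions: exposure continuation uses explicit
persistence arrows (`E0 -> E1`), and its effect contrast is continued
exposure vs quit. The reversed-causality scenario has no later outcome
by construction, so no exposure-effect RR exists to bias;
`bias_report()` returns undefined estimate rows for it (and for the
other outcome-less entry templates) and carries the scenario's content
in its signature values — the cross-lagged association a naive analysis
would misread as an exposure effect.

`bias_report()` contrasts, on the exact expected cohort: the true
standardized RR adjusting for all covariates known and unknown (computed
pre-selection), the crude RR, the observed-covariate Mantel–Haenszel and
IPW summaries, and full-covariate IPW — the last recovering the truth
wherever the full covariate set suffices.

## What the generator does and does not emulate

The engine produces exactly the world its diagram describes: binary
variables, discrete windows, faithful conditional tables, perfect
measurement, no missingness. Passing tests therefore demonstrate the
*logic* of selection processes — which structures distort which
estimators, and which corrections recover the truth — not performance on
real data, where variables are non-binary, effects drift over continuous
time, propensities need parametric smoothing and measurement error
interacts with selection. The named real-world illustrations in the
scenario descriptions are documentation, not calibrated models.

## Numerical and testing choices

Exactness claims are asserted at 1e-12 (joint mass conservation, printed
cell counts) and 1e-10 (IPW/standardization equivalence). The test
suite's sampling checks use seeded cohorts of n = 100,000 per scenario,
compared within 4 binomial standard errors per configuration and 4
log-RR standard errors per effect estimate; goodness-of-fit uses a
chi-square test at α = 0.001. These sizes make the whole suite run in a
few seconds while leaving the 4-standard-error bands far tighter than
any qualitative conclusion requires.
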