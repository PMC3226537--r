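---
title: "Methods: the prevcea decision model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the prevcea decision model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevcea)
```

## The decision problem and model

The model compares three situations of care for children followed from
birth to about age six: multifaceted primary asthma prevention (measures
against both airborne and food allergen triggers), unifaceted prevention
(exactly one measure), and the current situation (unstructured advice
plus symptomatic treatment). The perspective is the healthcare system;
the effect measure is the probability of avoiding an objective asthma
diagnosis at the end of follow-up; costs are in EUR indexed to 2009.

A decision tree fits this problem because asthma diagnosis is treated as
a single, stable endpoint over the six-year horizon — there are no
recurrent states to justify a Markov structure. Each strategy's chance
tree is fixed:

```
symptomatic? ── yes ── pharmacotherapy? ── ICS ──── diagnosis +/−
                                        ── none ─── diagnosis +/−
             ── no ──────────────────────────────── diagnosis +/−
```

Children either remain healthy or manifest asthma signs and symptoms;
symptomatic children may or may not receive pharmacotherapy; the
terminal outcome is the objective diagnosis. Asymptomatic children skip
the pharmacotherapy node but still face the diagnosis node, because at
this age a substantial share of children with asthma are symptom-free
yet test-positive. The pharmacotherapy branch is modelled as the ICS
flag, which is also the treatment input to the diagnosis rule; a child
on ICS is therefore always routed through the symptomatic/treated path
even if the recorded wheeze field is missing.

Branch probabilities are the empirical ratios
`n_event / (n_event + n_complement)` within the records reaching that
node. Terminal payoffs are the arithmetic mean of observed per-child
costs among the records on that path (an unbiased plug-in estimator
matching fold-back semantics) and the diagnosis outcome. Folding back
multiplies probabilities leaf-to-root; `enumerate_paths()` provides the
independent path-enumeration oracle against which `fold_back()` is
tested on randomly generated trees (tolerance 1e-9).

## The diagnosis rule

`classify_asthma()` implements a ten-row lookup over four fields: ICS
use in the three months before lung-function testing, wheeze in the same
window, bronchodilator reversibility, and bronchial hyperreactivity.

* Treated children (ICS+): symptomatology is not needed; any positive
  test implies asthma. The doubly-negative cell is genuinely ambiguous —
  treatment may have normalised the tests — and is resolved by a
  configurable rule (`diagnosis_config()`), run both ways as a
  sensitivity analysis. The default is `"negative"`, the conservative
  choice that ascribes no asthma without positive objective evidence.
* Untreated children: recorded wheeze is combined with reversibility,
  and hyperreactivity is consulted only where the table needs it.

The table is normative over any looser narrative summary of it: for
untreated children the rule is *not* simply "hyperreactivity decides",
because two rows (symptomatic with positive reversibility; asymptomatic
with negative reversibility) settle without the hyperreactivity result.
Fields in "not needed" cells are never read, and `is_evaluable()`
requires exactly the fields on the profile's lookup path — for ICS+
profiles both test results (the matched row is identified by both
columns), for ICS− profiles wheeze and reversibility always, plus
hyperreactivity off the two "not needed" rows. Records failing this are
excluded before modelling and counted in the run log. Ambiguous treated
doubly-negative cases are kept and scenario-flipped via the config
rather than excluded; excluding them can be emulated upstream by
filtering, so no second mechanism is provided.

## Per-protocol grouping and the current situation

The original trials randomised only intervention vs control, so the
unifaceted/multifaceted contrast is derived per protocol from observed
compliance: both measures adhered to → multifaceted, exactly one →
unifaceted, neither → control. Assignment is immutable. Compliance is
binarised per measure by the data producer (or the generator); the
package deliberately takes booleans, since no numeric adherence
threshold is published.

The current situation is the population mixture of PFH controls (weight
0.20) and NFH children (0.80), the strata ratio in the general
population. The mixture is applied to the folded-back subgroup
expectations; by linearity of expectation this equals record-level
pooling, and the weight is configurable.

## Costing

Unit prices carry a price year and are indexed to the target year
(default 2009) with configurable cumulative factors; the published
analysis cites standardised Dutch prices but prints neither prices nor
factors, so the packaged table holds round placeholder values (factor
1.0 for the target year) that make the pipeline runnable and are
clearly labelled as placeholders. Direct medical items accrue to every
child; intervention items (nurse visits, impermeable covers,
hypoallergenic formula, brochures) only to prevention recipients.
Money is rounded half-up to cents on output (`round_half_up()`), since
base R's banker's rounding is not reproducible money arithmetic. No
discounting is applied over the six-year horizon — the source analysis
never mentions it — and no societal costs are included.

## Empty cells

With empirical ratios, a chance node conditioned on an empty record
subset (an "empty cell") has no estimate. The builder first prunes
zero-probability branches exactly, so a cell that no record reaches
simply does not appear in the tree (a fully degenerate group folds to a
single unit-probability path). The policy in
`estimate_branch_probability()` then governs the residual cases:

* `additive` (default): 0.5 pseudo-count per branch, giving 0.5 for an
  empty pair; terminals below a smoothed cell fall back to the nearest
  ancestor's mean cost;
* `strict`: error naming the branch;
* `collapse`: drop the node.

Under the fixed three-level topology with pruning, reachable empty
cells cannot arise from data alone, so the policy is effectively a
guard; it is exposed, configurable and logged (`run_log.json` lists
every event) because the behaviour must be auditable.

## The synthetic generator: what it emulates, and what not

`generator_params()` states the world the tests run in:

* group sizes 259/53/12 PFH (the published per-protocol sizes) plus an
  NFH stratum of 500 — the published analysis does not print the NFH
  count, and 500 is a plausible natural-history cohort scale chosen
  once;
* per-group probabilities of wheeze, of ICS given wheeze, and of
  positive reversibility/hyperreactivity, the latter two optionally
  conditioned on symptomatic status (default in the packaged config:
  higher positivity among symptomatic children);
* independent Poisson counts per resource item — the simplest
  non-negative integer model, since no distributional detail is
  published;
* independent per-field missingness on the three diagnostic
  measurements, which exercises the evaluability filter;
* one master seed with documented per-group substreams
  (`(seed * 48271 + group_index) mod (2^31 − 1)`), so one group can be
  regenerated alone.

All rate values are placeholders, not estimates of the trial; the
published expected costs and probabilities are therefore *not*
recomputable here and live only as frozen fixtures
(`paper_expectations()`) feeding the CEA stage. A green synthetic test
establishes that the pipeline's estimators recover the generator's
parameters and that fold-back, mixing and CEA arithmetic are correct —
not that the trial's numbers are reproduced. Real data features the
generator does not emulate: correlated resource use and diagnosis
severity, informative missingness, compliance that correlates with
health status, and longitudinal wheeze phenotypes.

`analytic_strategy_expectation()` is the generator's closed-form twin:
it enumerates the finite outcome space (status × treatment × true tests
× missingness masks), conditions on evaluability exactly as the filter
does, and returns exact expectations. It is the oracle for
Monte-Carlo agreement (3 standard errors at n = 100,000) and for exact
equality against the pipeline under degenerate 0/1 parameters.

## Incremental analysis and thresholds

`incremental_analysis()` reports ΔC, ΔE and either the ICER or a
dominance label: strongly dominated (costlier, no more effective, one
inequality strict), dominant (the mirror image), equivalent (identical).
Dominance quadrants never report signed ratios, which are
uninterpretable. The headline ICER is also printed rounded to the
nearest €1,000. `efficient_frontier()` removes strongly dominated
strategies, then iteratively removes extendedly dominated ones (ICER
above the next, more effective option); collinear strategies with equal
consecutive ICERs are all retained. `threshold_sweep()` evaluates
`NMB(λ) = λ·E − C` on a grid (defaults €0–€70,000 in €1,000 steps — the
published range endpoints, with the step a package choice) and records
the argmax per point; ties break toward the lower-cost strategy (then
alphabetically, for determinism), the conservative payer convention.

## Numerical choices

* Chance-node probabilities must sum to 1 within 1e-9; violations error
  with the node label.
* Fold-back vs enumeration agreement is asserted at 1e-9; the analytic
  tree equals the analytic expectation to the same tolerance.
* Money: half-up rounding to cents at output boundaries only
  (`index_price()`, `child_cost()`); intermediate expectations stay at
  full double precision. Probabilities print with 5 decimals, money
  with 2.
* Degenerate inputs: an empty cohort is an error for tree building but
  fine for filtering/grouping; probability-0/1 parameters produce
  single-path trees and exact expectations.

## Known limitations

* No probabilistic sensitivity analysis beyond the diagnosis-rule
  toggle; no acceptability curves, QALYs, discounting or societal
  costing — all outside the model's published scope.
* The per-protocol regrouping inherits any confounding between
  compliance and prognosis; the package reproduces the design rather
  than correcting it.
* The packaged prices and generator rates are placeholders; any
  substantive use requires a real price table and cohort.
* The €70,000 threshold ceiling is adopted as given; its provenance is
  not documented in the source analysis.
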