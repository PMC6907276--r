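---
title: "Models and methods behind vdthealth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vdthealth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdthealth)
```

`vdthealth` models periodic health-surveillance examinations of
administrative employees who work at video display terminals. This vignette
is the package's own account of its models: the generative cohort model, the
Bayesian-network engine, the proportion screening, the influence-diagram
cost-utility analysis, and the numerical and design choices behind each.

## The generative cohort model

Raw surveillance examinations are confidential, so the package ships a
generative stand-in. An exam record is one disorder class
(`none`, `musculoskeletal`, `ophthalmological`, `nervous`, `cardiovascular`,
`other`) and seven binary clinical attributes. Each attribute has a
designated *risk state* (man, age ≥ 39, overweight, variable sleep, no
regular physical activity, smoker, alcohol user); the generative parameters
are the class prior and, per (class, attribute) pair, the probability of the
risk state given the class.

Records are sampled class-first, then each attribute independently given the
class. Conditional independence given the disorder is an assumption, not an
observation: only class-conditional *marginals* are published for this
population, and the naive model is the maximum-entropy completion of those
marginals. It also matches the target-conditional family the augmented naive
Bayes learner searches over, which is precisely why `generate_cohort()`
exposes a `couple` hook that plants one attribute–attribute dependency
(a noisy copy with a chosen agreement rate) — without it, structure-learning
tests could never see a true augmentation arc.

Calibration choices in `default_population_spec()`:

* P(no disorder) = 1942/2453; within the disordered remainder the named
  classes take shares 29.08% / 14.66% / 10.92% / 9.97%, and `other` absorbs
  the rest (35.37%), making the prior sum to 1 by construction. `other` has
  no published conditional profile and defaults to the no-disorder column.
* Age, BMI, smoking and alcohol are dichotomised as in the source tabulation
  (age cut at the population mean of 39 years; smoker and alcohol-user
  include sporadic use).
* One published row is internally inconsistent: the no-disorder activity
  column prints 68.42% active and 34.58% inactive (sum 103%). Since the
  generator parameterises the risk state, the printed *inactive* figure
  (0.3458) is used at face value. Similarly the nervous-class age row sums to
  99.82%; the printed ≥ 39 figure (0.6553) is used.
* The default cohort size is n = 2453, mirroring the study; class counts are
  multinomial draws, not fixed quotas, so per-class n varies between seeds.

What the generator deliberately does **not** emulate: continuous age and BMI,
repeat examinations of the same employee over time, employment-sector
stratification, missing values, and any attribute–attribute dependence beyond
the optional planted coupling. Tests passing on this cohort therefore
validate the *estimators and pipeline*, not the epidemiology of any real
workforce: in real records the conditional-independence assumption will be
violated in unknown ways, which is exactly what the augmentation arcs of the
learned network are there to absorb.

## The Bayesian-network engine

A network is the triplet (X, G, P): categorical variables with ordered state
sets, a DAG, and one CPT per node; the joint factorises as the product of
each node's CPT given its parents. Ordered state sets matter — they are the
deterministic tie-break for classification.

**Structure learning.** `learn_abn_structure()` returns the naive star
(disorder → every attribute) plus augmentation arcs among attributes chosen
by conditional mutual information given the target,

CMI(Xi; Xj | T) = Σ p(t, xi, xj) · log [ p(t) p(t, xi, xj) / ( p(t, xi) p(t, xj) ) ],

estimated from empirical frequencies and measured in **nats**. Pairs with
CMI ≤ `cmi_threshold` are pruned; a maximum-weight spanning forest (Kruskal)
is extracted from the survivors; each tree is directed away from its
lexicographically smallest member. Every attribute thus has at most one
attribute parent, and the augmentation subgraph is acyclic by construction.
The exact augmentation scheme of the proprietary tool that popularised the
"augmented naive Bayes" name is unpublished, so this CMI-forest variant —
the standard algorithm of that family, with a threshold that can prune the
tree down to a forest or to nothing — is the package's own design choice.
The default threshold of 0.01 nats is likewise a choice: at the cohort sizes
used here (2,000–20,000 records) the empirical CMI of truly
conditionally-independent binary pairs stays well below it, while even a
weak planted coupling rises well above it. Ties in edge weight are broken by
lexicographic pair order, so learned structures are deterministic.

**Parameters.** `fit_mle()` estimates each CPT row as
`(count + smoothing) / (row total + smoothing · n_states)`. The default
`smoothing = 0` is the plain maximum-likelihood frequency estimator; a parent
configuration never observed under zero smoothing yields a **uniform row**
(the documented fallback — preferable to NaN, and harmless in inference
because such configurations also have zero probability upstream whenever the
parent CPTs were fitted from the same data).

**Inference.** `posterior()` is exact variable elimination with a min-degree
elimination order (ties alphabetical). The networks here have ≤ 10 nodes, so
exactness is cheap; a completely independent full-enumeration oracle lives in
the test suite and the two are required to agree to 1e-12 across randomly
generated networks. Evidence with probability zero raises an explicit error
rather than returning NaN. `classify()` is the MAP state of the target with
ties broken by declared state order; `sensitivity()` perturbs a source
state's marginal by ±delta (other states rescaled proportionally, implemented
as a likelihood-weight factor on the source node) and reports the signed
change in a target-state posterior. Perturbations that push the marginal
outside [0, 1], or sources with degenerate (0/1) marginals, are errors.

CPT normalisation and posterior normalisation are checked to 1e-9; the
VE-vs-enumeration agreement is asserted to 1e-12. These are numerical-noise
bounds, not statistical tolerances.

## Proportion screening

`screen_risk_factors()` compares each attribute's risk-state proportion in a
disorder class against the no-disorder reference with a pooled two-proportion
z-test, two-sided, no continuity correction. The test family in the source
tabulation is unnamed, and its printed statistics cannot be recovered from
the printed proportions and group sizes under any standard two-sample
proportion test — so the printed statistics are treated as unverifiable, and
the implementation is validated instead by (a) an exact cross-check against
`prop.test(correct = FALSE)` (z² = chi-square) and (b) a type-I-error
calibration: under the null, with two groups of 200 over 2,000 seeded
replicates, the rejection rate at alpha = 0.05 must land in [0.035, 0.065].
A degenerate pooled proportion (0 or 1) forces the two sample proportions to
be equal and is defined as z = 0, p = 1. No multiplicity adjustment is
applied by default, matching the source analysis; Bonferroni is available via
`adjust = "bonferroni"`.

## The protocol influence diagram

The protocol decision is modelled as an influence diagram: a decision node
over strategies, one probabilistic node per diagnostic test (performed with
`perform_probability`, default 1), two utility nodes per test (time in
minutes, money in USD), and two additive linear utility nodes aggregating
each axis. Because the utilities are additive and the test nodes independent,
expected utility is just Σ perform_probability · cost per axis, and with all
probabilities 1 it collapses to a plain sum — `evaluate_strategy()` — so the
diagram is evaluated in closed form rather than by graph propagation.

The published total-utility row equals money (USD) + time (minutes)
numerically, i.e. an implicit valuation of **1 USD per minute** of specialist
time. Rather than hard-code the coincidence, `minute_value` is an explicit
parameter (default 1): total = money + minute_value · time, affine in
`minute_value` with slope equal to the time utility.

Two published cells need care:

* Strategy B's printed total (32.4933 USD) contradicts its own money and
  time rows (11.4933 + 31 = 42.4933). The package reports the internally
  consistent value and the tests document the exclusion.
* The printed "total cost reduction" row matches *time-only* reductions for
  B–E (11/23/31/41%) but the *total-utility* reduction for F (54%).
  `reduction_report()` therefore always reports both axes
  (`reduction_total`, `reduction_time`), raw and rounded to integer percent
  for display.

## Pipeline and reproducibility

`run_reproduction()` chains cohort → structure/CPTs → diagnostic profiles →
screening → strategy report, writing CSV/JSON artifacts and a one-line-per-
stage summary log. A single master seed is fanned out deterministically to
per-stage child seeds (a fixed affine map kept below 2³¹), so a stage rerun
standalone from a previous stage's artifacts reproduces its output exactly;
identical configurations produce byte-identical artifacts. Cohort CSVs are
validated on read: a bad state token is rejected with its row and column, and
a header-only file is an empty cohort, not an error.

## Problem sizes used in the checks

The test suite validates stochastic claims at sizes chosen to make
3-standard-error bounds meaningful while keeping the suite quick: 50,000
records for prior/parameter recovery, 20,000 for structure-learning
behaviour and the flagship calibration check (where the musculoskeletal
subgroup is ~1,200 records, giving a binomial SE of about 1.3 percentage
points on the 71.81% age conditional), 200 random ≤ 6-node networks for the
inference oracle, and 2,000 replicates for the z-test calibration. These are
the package's own choices of scale.

## Known limitations

* The cohort model is synthetic and conditionally independent by
  construction; it cannot certify behaviour on dependent real-world records
  beyond what the planted-coupling tests exercise.
* Structure learning restricts augmentation to a forest (one attribute
  parent per attribute); denser dependence would be approximated, not
  represented.
* Inference is exact and therefore exponential in treewidth in principle;
  the package targets the ≤ 10-node networks of this domain, not large
  graphs.
* Costs are plain magnitudes (minutes, USD); no currency conversion,
  discounting, or salary re-derivation is attempted, and scheduling of the
  medical agenda (examinations per day) is out of scope.
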