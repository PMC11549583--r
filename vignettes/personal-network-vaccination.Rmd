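---
title: "Methods: personal networks, vaccination assortativity, and two-level models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personal networks, vaccination assortativity, and two-level models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnavax)
```

## The study design this package models

An egocentric (personal) network study samples respondents (*egos*) —
here through respondent-driven link-tracing chains started from a handful
of seeds — and asks each to nominate up to 25 social contacts (*alters*),
to describe each alter (sex, age, education, relationship status,
COVID-19 vaccination status), to characterise the ego–alter relationship
(emotional closeness on four levels; face-to-face meeting frequency on
seven), and to report which pairs of alters know each other
(acquaintances / casual friends / close friends). Egos additionally report
their own attributes and their sources of health information, from five
options spanning legacy media (central TV, local press) and online media
(search engines, social media, influencers).

The scientific question is whether an ego's reliance on online media for
health information is associated with the vaccination status of the people
around them, once composition and structure of the personal network are
controlled for. Because alters are nested in egos and all alter data are
reported *by* the ego, inference uses a two-level random-intercept
logistic regression.

## Derived variables

All derivations are deterministic (`derive_study()`):

* **Media category.** `traditional` if the ego's sources are a non-empty
  subset of {central TV, local press}; `online` if a non-empty subset of
  the three online options; `both` if the sources straddle the two groups;
  missing when no source is recorded. `traditional` is the modelling
  reference level. The partition is exhaustively tested over all 31
  non-empty source subsets.
* **Tie binarization.** Any reported alter–alter relation counts as an
  edge; an unreported pair is a non-edge. Tie strength is deliberately
  discarded — the downstream measures are defined on the binary graph.
* **Ego–alter intensity.** The product of "feels very close" (closeness =
  `very_close`) and "meets at least twice a month" (`every_2_weeks`,
  `weekly` or `daily`). The boundary puts `once_month` at 0: the
  complementary label is "less than twice a month", which forces monthly
  meetings below the cut.

## Structural measures

Computed on the binarized alter graph with the ego excluded (its presence
is redundant: it is tied to every alter by construction):

* **Size** — number of alters; **density** — edges over `n(n-1)/2`;
  **components** — connected components, isolates counting as stand-alone
  components. The alter graph is undirected, so "strong" components
  coincide with ordinary ones.
* **Normalized betweenness** — Freeman shortest-path betweenness divided
  by `C(n-1, 2)`, the maximum number of pairs a node could sit between, so
  scores are comparable across network sizes. Computed on the possibly
  disconnected graph; unreachable pairs contribute zero; any node of a
  graph with at most two nodes scores zero. The implementation (igraph) is
  checked in the tests against an exhaustive path-enumeration oracle on
  every labeled graph with up to 4 nodes and on sampled graphs with 5–7
  nodes, to 1e-12.

## The vaccination assortativity score

For alter *i* of ego *j*:

$$\mathrm{score}(i) = \frac{\#\{\text{vaccinated known-status neighbours of } i\}}{\#\{\text{known-status neighbours of } i\}} - \frac{\#\{\text{vaccinated known-status alters of } j\} \setminus i}{\#\{\text{known-status alters of } j\} \setminus i}$$

Choices a user should know about:

* Alters with missing vaccination status are removed from numerator and
  denominator of **both** proportions — the rule that keeps both
  proportions well-defined and unbiased under missingness completely at
  random.
* The score is **missing** — never coerced to zero — for isolates, for
  alters whose every neighbour has unknown status (an unusable
  neighbourhood is equivalent to having none), and in networks with fewer
  than two known-status alters.
* If every known status is identical, every defined score is exactly 0,
  and under random relabelling of statuses on a fixed graph the expected
  score is 0; both properties are tested (the latter by Monte Carlo with
  4000 shuffles against a 3-standard-error band).
* A worked numerical case used in the tests: a 25-alter network with 14
  vaccinated, focal alter vaccinated with 9 neighbours of whom 6 are
  vaccinated, gives exactly `6/9 - 13/24 = 0.125` (intermediates 0.667 and
  0.542).

The mean of the defined scores summarises a network; the score is also a
level-1 predictor in the models (z-scored like the other numerics).

## Cohort construction

`filter_networks()` applies the eligibility rule: an alter is *eligible*
when its vaccination status is known **and** it has at least one tie
(isolates have no defined assortativity score). A network is retained when
it has at least `min_alters = 15` eligible alters — the boundary is
inclusive. Degrees are evaluated once on the original binarized graph, not
recomputed after removing ineligible alters; structural measures
(size, density, components, betweenness) are likewise computed on the full
nominated network before eligibility filtering. Both are the plain reading
of a one-pass exclusion rule; nothing in the downstream code depends on
the alternative, and the frame-construction code is the single place to
change if a re-evaluated variant is wanted.

`model_frame()` then builds the analysis table: one row per eligible alter
with complete data on every model variable (complete-case, no imputation),
dropping egos with missing media category. Numeric predictors are
mean-centred and scaled — alter-level ones over the retained alter rows,
ego/network-level ones over the retained egos, so that each ego
contributes once to its own scaling; sample (n−1) SD by default, with a
population-SD option. Binary indicators, ego–alter intensity and the
outcome stay on their 0/1 scale. A numeric predictor with zero spread
(possible in tiny or homogeneous studies, e.g. every network a single
component) is centred to zero with a warning rather than aborting the
frame; the corresponding fixed effect is then aliased and dropped by the
fitting routine. The leave-one-out vaccinated proportion `loo_prop` —
used by the cluster-robust model in place of a random intercept — is
computed over the rows of the frame itself.

## Models

`fit_random_intercept_logit()` wraps a maximum-likelihood (Laplace)
`lme4::glmer` fit with the deterministic `bobyqa` optimizer, so repeated
runs on the same frame are bit-stable. Reported per model:

* Wald 95% confidence intervals on the log-odds scale exponentiated to
  odds ratios (no profile likelihood), with two-sided normal p-values and
  no multiplicity adjustment — one Wald test per coefficient.
* The random-intercept variance and the **latent-scale ICC**
  `sigma^2 / (sigma^2 + pi^2/3)`; with the logistic residual variance
  fixed at `pi^2/3` a variance of 0.83 yields 0.2015, i.e. 0.2 at one
  decimal.
* **Nakagawa marginal and conditional R²** with the logit
  distribution-specific variance `pi^2/3`: marginal = variance of the
  fixed linear predictor over total latent variance; conditional adds the
  intercept variance to the numerator. Conditional ≥ marginal always.

Non-convergence is flagged on the result rather than raised. A constant
outcome, or a categorical predictor that perfectly predicts the outcome,
raises a separation diagnostic naming the predictor before fitting.

`model_suite()` fits the standard four-model comparison — null
(random intercept only), attributes-only, network-only (intensity,
betweenness, assortativity, size, density, components), full (the union) —
and emits a tidy long table plus a forest-plot-ready OR table with
reference levels marked.

`fit_cluster_robust_logit()` is the single-level check: a plain logistic
fit with cluster-robust covariance by ego (`sandwich::vcovCL`), CR1
small-sample scaling by default (configurable to CR0), with `loo_prop`
standing in for the absent random intercept.

`bivariate_suite()` runs the routine companions: chi-square tests of alter
vaccination against ego vaccination and media use, an ego-level
vaccination-by-media test with a Fisher fallback when expected cell counts
fall under 5, pooled-variance two-sided t tests of the assortativity score
by alter and by ego vaccination, and a chi-square of assortativity
quartiles against the six media-by-ego-vaccination groups.

## The synthetic generator

Field data of this kind are rarely shareable, so `generate_study()` is a
first-class module: it produces studies with the same shape and marginals
and records ground truth sufficient to score any estimator.

What the default (`lerestilike` profile) emulates: 83 egos; 15–25 alters
each with the size distribution skewed to 24–25 (realized mean ≈ 24);
Bernoulli alter graphs whose per-network edge probability is drawn from a
moment-matched Beta with mean 0.65 and SD 0.21; ego marginals (age
53.3 ± 15.9, 52% female, education 9.7 ± 1.78 on the 1–13 ordinal grid via
a discretized normal, 56% employed, 12.5% single, 78% vaccinated) and
alter marginals (age 52.6 ± 16.1, 52.5% female, education 9.35 ± 1.93,
20.4% single); closeness and meeting-frequency distributions chosen so
that ego–alter intensity has mean 0.22; media split 17/33/45%
traditional/online/both with 5% missing; 11.3% missing alter vaccination;
a 1% per-alter isolation probability (dense Bernoulli graphs essentially
never fragment, but field networks do — this reinstates isolates and a
components mean above 1); and link-tracing referrals from 6 seeds with
76% status-concordant referral and a 45.8% refusal rate. Generating
coefficients default to the log odds ratios of the published full model;
the intercept is the log-odds of alter vaccination at covariate means
(`qlogis(0.64)`).

Vaccination is assigned by the two-level logistic model with ego
intercepts drawn `N(0, 0.913^2)`, then optionally updated by *contagion*:
a fixed number of synchronous rounds in which each alter's log-odds gains
`strength * (neighbour vaccinated fraction - 0.5)` before a fresh
Bernoulli draw. Missingness is applied last.

What the generator does **not** emulate, hence what passing tests do not
show about real data:

* Ego and alter attributes are drawn independently — no joint structure
  (education × media use, age × network size, ...), because the source
  material gives marginals only.
* Alters are ego-scoped; the same real person nominated by two egos is two
  records. No name-generator behaviour (recall, false consensus) is
  modelled.
* In dense networks every alter's neighbourhood resembles the whole
  network, so the per-alter assortativity score is pinned near zero
  whatever the contagion does; the contagion-detectability test therefore
  runs at density 0.12, where neighbourhoods genuinely differ. At the
  default density the generated mean score is positive but smaller than
  the field value (~0.02). A two-block planted-partition graph option
  exists for explicitly subgroup-structured networks.
* Contagion feeds network-level vaccination rates back into individual
  draws, which *amplifies* ego-level effects relative to their generating
  coefficients; parameter-recovery checks therefore switch contagion off.

Determinism: a seed is mandatory; identical config and seed give
byte-identical output. The link-tracing simulator accepts
`max_respondents` because a chain allowed to exhaust the population is
forced into discordant referrals once the minority-status pool drains —
real recruitment stops at a target sample size.

## Numerical and testing choices

* Standardization uses the sample (n−1) SD; a population-SD option exists
  because the convention is ambiguous in most write-ups.
* The betweenness normalizer is `C(n-1,2)` (undirected, endpoints
  excluded); betweenness of any node in a ≤2-node graph is 0.
* Duplicate undirected ties (including both orientations) collapse to one
  with a warning; unparseable ordinal labels become missing with a
  warning, never dropped rows.
* Optimizer: `bobyqa` with lme4 defaults; fits are deterministic given the
  frame.
* Test problem sizes: parameter recovery uses 50 replicates at 200 egos ×
  25 alters (bias of the mean media-online estimate < 0.15 on the
  log-odds scale); the sigma-zero degeneration check uses 150 egos with
  the generating effects restricted to the fitted predictors (otherwise
  omitted ego-level effects are absorbed into the intercept variance and
  the comparison is confounded); marginal-fidelity checks use 400 egos
  with 3-standard-error bands; oracle checks are exhaustive at n ≤ 4 and
  sampled (300 graphs) at n = 5–7.

## Limitations

* Coefficient estimates from the synthetic default profile are not a
  reproduction of any published table — the underlying field data are not
  public, and the generator's independence assumptions guarantee the
  joint distribution differs.
* The assortativity score is a descriptive difference of proportions; it
  does not separate selection from influence, and no Newman-style edge
  assortativity, ERGM or SAOM machinery is provided.
* No imputation: all models are complete-case, matching the design the
  package implements.
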