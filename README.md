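# pnavax

Personal-network analysis of COVID-19 vaccination: who is vaccinated in a
respondent's social circle, and how does that relate to the respondent's
media diet and the structure of their network?

`pnavax` is an R package for egocentric (personal) network studies of a
binary health behaviour. It targets the design in which each surveyed
respondent (*ego*) nominates up to 25 social contacts (*alters*), reports
their attributes and the ties among them, and is recruited through
respondent-driven link-tracing chains. The package covers the full analysis
path: data model and validation, derived variables, structural measures,
a per-alter assortativity score, cohort filters, two-level random-intercept
logistic regression, and a synthetic-data generator with known ground truth
so every stage is testable without access to field data.

## The statistics at its core

**Vaccination assortativity score.** For alter *i* in the network of ego
*j*, with *i* excluded from both proportions and alters of unknown status
excluded throughout:

```
score(i) = (vaccinated fraction of i's network neighbours)
         - (vaccinated fraction of all of j's other alters)
```

A positive score means *i*'s direct neighbours are vaccinated above the
network's leave-one-out base rate — assortative mixing on the trait. The
score is undefined (missing, never silently 0) for isolates and in networks
with fewer than two known-status alters.

**Two-level model.** Alter vaccination status *y_ij* is modelled as

```
logit P(y_ij = 1) = x_ij' B + u_j ,   u_j ~ N(0, sigma^2)
```

with alter-level predictors (sex, education, age, single, ego-alter
intensity, normalized betweenness, assortativity score) and ego/network
level predictors (sex, education, age, employment, vaccination, media
category with *traditional* as reference, network size, density,
components). The intraclass correlation uses the latent-threshold logistic
convention `ICC = sigma^2 / (sigma^2 + pi^2/3)`, and explained variance is
reported as Nakagawa marginal / conditional R². A single-level logistic
variant with ego-clustered robust standard errors (plus the leave-one-out
vaccinated proportion as predictor) is also provided.

## Worked example

```r
library(pnavax)

cfg   <- load_profile("lerestilike", seed = 2026)  # synthetic study profile
study <- generate_study(cfg)$study
study
#> <study_data> 83 personal networks, 1994 alters, 13990 ties, 31 referral edges

filt  <- filter_networks(derive_study(study))      # >=15 eligible alters
frame <- model_frame(filt$study)                   # standardized 2-level table
fit   <- fit_random_intercept_logit(frame)
fit
#> <mixed_fit> 1648 obs in 77 ego groups; sigma2_ego=0.849, ICC=0.205
#>   R2 marginal=0.294 conditional=0.439  logLik=-852.3
#>               term estimate     se       z  p_value    or or_low or_high
#> ...
#> 13  ego_vaccinated  2.20507 0.3049  7.2312 4.79e-13 9.071  4.990  16.490
#> 14     mediaonline -1.11675 0.3931 -2.8408 4.50e-03 0.327  0.151   0.707
#> 15       mediaboth -0.80711 0.3621 -2.2291 2.58e-02 0.446  0.219   0.907
```

Reading the output: each row is an odds ratio for alter vaccination. Here
`mediaonline` = 0.33 means alters of egos who rely only on online media for
health information have roughly a third the odds of being vaccinated
compared with alters of traditional-media egos, holding the rest fixed —
the generating profile plants exactly such an effect (log OR `log(0.37)`),
and the ego-level variance component (`sigma2_ego` 0.85, ICC 0.21) reflects
the planted random intercept (SD 0.913).

Single measures are available directly:

```r
net <- get_network(study, "e001")
network_assortativity(net)          # per-alter scores for one network
normalized_betweenness(build_alter_graph(net))
icc_latent(0.83)                    # 0.2015...
```

A one-call orchestration, `run_pipeline(study, "out/")`, persists every
stage (validation, structure, assortativity, filter funnel, model frame,
four-model comparison suite, cluster-robust fit, bivariate tests,
descriptives, forest table) as CSV plus a JSON manifest with file hashes;
re-running on the same input reproduces identical hashes.

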