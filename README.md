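# rdsmix

Analysis of one-day contact-diary surveys collected by **respondent-driven
sampling (RDS)**. In such surveys each respondent records how many people
came within arm's length during one day — while travelling, at different
locations and while sharing meals — and then invites up to four recent
contacts to do the same. The result is a forest of recruitment trees whose
links are real social ties, which makes it possible to ask questions that
egocentric contact surveys cannot: do people mix with others of similar
age, gender, education or contact degree? How far along a recruitment
chain does that similarity persist? How strongly are respondents within
one tree clustered, and what does the sample imply for the underlying
population once the degree-biased inclusion of RDS is corrected?

`rdsmix` is aimed at infectious-disease epidemiologists and survey
statisticians working with (web)RDS contact data. It implements:

* **Recruitment forests** — reconstruction from recruiter→recruit records
  with wave assignment, coupon-limit and cycle validation, and
  GraphML/DOT export (`build_forest()`, `export_forest()`).
* **Diary measures** — the degree of respondent *i* is
  *d<sub>i</sub>* = Σ travel contacts + Σ location contacts, censored at a
  cap (default 500/day; contacts while eating capped at 75/day), with
  log(x+1) transforms and symptom indicators (`derive_measures()`).
* **Degree distribution** — maximum-likelihood negative binomial fit in
  the (μ, k) parameterisation, Var(X) = μ + μ²/k
  (`fit_negative_binomial()`).
* **Assortativity by tree distance** — Pearson's *r*, the phi coefficient
  and Spearman's rank correlation over all pairs of participants at tree
  distance *d* within a component, with distances ≥ 5 lumped and Fisher-z
  confidence intervals (`pairs_at_distance()`, `pair_correlation()`,
  `distance_profile()`, `linked_pair_table()`).
* **Intraclass correlation** — ICC = σ²<sub>u0</sub> /
  (σ²<sub>u0</sub> + σ²<sub>e</sub>) from an intercept-only two-level
  model fitted by REML on the unbalanced one-way layout
  (`fit_variance_components()`, `icc_from_components()`, `icc_table()`).
* **RDS-II inference** — Volz–Heckathorn estimates
  p̂<sub>A</sub> = (Σ<sub>i∈A</sub> 1/d<sub>i</sub>) / (Σ<sub>i</sub>
  1/d<sub>i</sub>) plus sample-composition curves over waves and sample
  size (`vh_estimate()`, `composition_curves()`).
* **Markov-assumption test & synthetic data** — Monte-Carlo simulation of
  a first-order autoregressive trait on a fixed forest
  (`simulate_ar1_on_forest()`; under first-order dependence the
  distance-*d* correlation decays as ρ<sup>d</sup>), and a full synthetic
  survey generator — coupon-limited branching recruitment, assortative
  attributes, negative binomial degrees — for validation by parameter
  recovery (`simulation_config()`, `generate_dataset()`).

`run_report()` chains the whole pipeline and writes a deterministic
bundle of delimited tables, JSON summaries and a GraphML forest.

## Worked example

```r
library(rdsmix)

cfg     <- simulation_config(rng_seed = 2026)   # defaults emulate the pilot survey
records <- generate_dataset(cfg)
records <- derive_measures(zero_fill(records))
forest  <- build_forest(records)
forest
#> <recruitment_forest> 172 participants, 80 components (largest 10), max wave 6

fit_negative_binomial(records$degree[records$completed])
#> Negative binomial fit (n = 172)
#>   mean mu   = 77.680 (SE 7.242)
#>   disp k    = 0.6747 (SE 0.0652)
#>   logLik    = -912.677   converged: TRUE
```

The fitted mean (≈ 78 contacts/day) and dispersion (k ≈ 0.67, strongly
overdispersed) recover the generating law (μ = 88.2, k = 0.57) within
sampling error at this small sample size. Recruiter–recruit
assortativity:

```r
linked_pair_table(records, forest)[, 1:7]
#>             variable statistic estimate ci_low ci_high df       p
#> 1                age   pearson    0.421  0.236   0.576 90 2.9e-05
#> 2             gender       phi    0.215  0.011   0.402 90 3.9e-02
#> 3          education  spearman    0.283  0.082   0.461 90 6.4e-03
#> 4         degree_log   pearson   -0.011 -0.215   0.194 90 9.2e-01
#> ...
```

Age, gender and education are assortative (linked individuals resemble
each other); degree mixes at random — exactly the pattern the generator
was configured to produce. Clustering within recruitment trees:

```r
icc_table(records, forest)
#>             variable    icc sigma2_between sigma2_within   n
#> 1                age 0.2912         9.4083        22.897 172
#> 2             gender 0.1840         0.0430         0.191 172
#> 3          education 0.5003         0.3101         0.310 172
#> 4         degree_log 0.0412         0.0912         2.123 172
#> ...
```

An ICC of 0.29 for age means two random members of the same tree are
expected to correlate 0.29 — high homogeneity within components, hence a
less representative sample per observation. Degree-weighted population
estimates:

```r
vh_estimate(records, "education")
#> Volz-Heckathorn estimate for 'education' (n = 167, excluded 5; weights = 1/degree)
#>           category    raw     vh
#> 1         bachelor 0.6108 0.6505
#> 2   below_bachelor 0.2335 0.1408
#> 3 master_or_higher 0.1557 0.2087
```

The VH column reweights each respondent by 1/degree, correcting the
tendency of RDS to oversample well-connected individuals.

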