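---
title: "Methods: RDS contact-diary analysis in rdsmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RDS contact-diary analysis in rdsmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdsmix)
```

## The data and the model

Respondent-driven sampling (RDS) recruits a survey sample along real
social ties: each respondent ("recruiter") hands a small number of
coupons — four here — to contacts met recently, and every recruit may do
the same. The bookkeeping of who recruited whom yields a directed
**recruitment forest**: each participant has at most one recruiter, seeds
have none, waves count recruitment steps from the seed, and each weakly
connected component is one recruitment tree. `build_forest()` enforces
exactly these invariants (in-degree ≤ 1, out-degree ≤ coupon limit,
acyclicity, wave of child = wave of parent + 1) and labels components by
their smallest member identifier so that results are deterministic under
row reordering.

Each respondent's one-day contact diary gives a **degree**: the sum of
contacts reported while travelling (4 transport modes) and at named
locations (7 settings). Contacts while sharing meals are recorded
separately and do not enter degree; neither does the household roster
(household members met at home are counted through the *home* location).
Respondents leave non-applicable fields empty, so for everyone who
completed the questionnaire an empty count is read as zero
(`zero_fill()`); non-completers keep missing values and drop out of
count-based analyses. Degree and eating totals are censored at
configurable caps (defaults 500 and 75 contacts/day) representing the
highest plausible single-day values; raising a cap can only increase a
derived degree (censoring is monotone, and the property suite checks
this).

## Assortativity at tree distance

Mixing is measured by correlating attribute values over pairs of
participants in the same component: Pearson's *r* for integer-valued
variables, the phi coefficient (Pearson on 0/1 indicator codes) for
binary ones, Spearman's rank correlation for ordinal ones. Count
variables are log transformed first. Two pair orientations are exposed:

* **directed** — ordered (ancestor, descendant) pairs exactly *d*
  recruitment steps apart; at *d* = 1 these are the recruiter→recruit
  pairs, which is the mode used for the standard linked-pair table
  (`linked_pair_table()`).
* **symmetrized** (default for distance profiles) — every unordered pair
  at undirected tree distance *d*, entered once per orientation. Pairs at
  *d* ≥ 2 may straddle a common ancestor (siblings, cousins) and have no
  natural direction, so the symmetric estimate is the defensible default;
  it is invariant to orientation by construction.

Distance profiles report one estimate per distance 1 … 4 and lump
distances ≥ 5, where pair counts become small. Confidence intervals use
the Fisher z-transform with *n* equal to the number of unordered pairs;
pairs sharing an individual are not independent, so these intervals are
approximate — a conservative reading is advised and the replicate-based
envelope from `simulate_ar1_on_forest()` is the better yardstick for
distance profiles. P-values are the classical t-test for Pearson and
Spearman and the one-degree chi-square *n·r²* for phi; no
multiple-testing adjustment is applied. Pairs with a missing value on
either side are dropped listwise per variable, and the drop count is
reported, so degrees of freedom legitimately differ between rows of the
linked-pair table. The household-size row excludes respondents reporting
more household contacts than a configurable cap (default 500), mirroring
the single implausible report in the motivating survey.

### Log convention

Counts include zeros, so the package defaults to log(x + 1), which keeps
every respondent in the analysis; `log_convention = "log_positive"`
switches to log(x) with zeros excluded for sensitivity checks. This is a
deliberate design choice: dropping zero-degree respondents would
systematically remove the least-connected individuals from exactly the
analyses that study connectivity.

## Intraclass correlation

Respondents in one recruitment tree resemble each other, which inflates
the variance of naive estimates. The intraclass correlation for the
intercept-only two-level model *y<sub>ij</sub>* = μ + *u<sub>i</sub>* +
*e<sub>ij</sub>* is

ICC = σ²<sub>u0</sub> / (σ²<sub>u0</sub> + σ²<sub>e</sub>),

the expected correlation of two random members of the same component.
`fit_variance_components()` fits the unbalanced one-way layout by REML.
The implementation profiles the restricted likelihood in the variance
ratio θ = σ²<sub>u0</sub>/σ²<sub>e</sub>: for fixed θ the GLS mean and
the residual variance are closed-form, leaving a one-dimensional
criterion minimised over log θ (tolerance 1e-8) with an explicit boundary
check at θ = 0. A negative between-component estimate is therefore
truncated at zero and the ICC reported as 0. On balanced data the interior
REML solution coincides with the closed-form ANOVA estimator — the test
suite requires agreement to 1e-6 — and the ANOVA method-of-moments
estimator is available as `method = "anova_mom"` for cross-checking.
Binary and ordinal variables are fitted as numeric codes in the linear
model, so their variance components are on the coding scale.

One reference inconsistency is worth recording: in the published ICC
table that motivated this module, the gender row prints an ICC of 0.203
alongside components 0.049 (between) and 0.203 (within), yet
0.049/(0.049 + 0.203) ≈ 0.194. The package always reports the formula
value; the worked-example tests therefore check the age, log-degree and
log-eating rows, whose printed ICCs are consistent with their printed
components, and exclude the gender row.

## Volz–Heckathorn estimation

RDS reaches well-connected people more often — inclusion probability is
roughly proportional to degree — so the RDS-II (Volz–Heckathorn)
estimator weights each respondent by 1/d<sub>i</sub>:

p̂<sub>A</sub> = (Σ<sub>i∈A</sub> 1/d<sub>i</sub>) / (Σ<sub>i</sub> 1/d<sub>i</sub>).

The diary degree (censored) is the only network-size measure such a
survey collects and is the default weighting variable; `degree_source`
accepts any other column, and the chosen source is echoed in the output
so downstream readers can see which definition was used. Seeds are
included by default (exclusion is a flag): they are few, and the
estimator's weighting logic applies to them as to anyone else.
Individuals with missing attribute or non-positive degree are excluded
and counted. The estimate is invariant to rescaling all degrees and
collapses to the raw sample share when degrees are equal (verified to
numerical precision in the tests). Composition curves over waves and over
accumulating sample size (in wave-major, then identifier order — the
deterministic stand-in for unavailable timestamps) show whether the
sample composition approaches equilibrium or still carries the imprint of
seed selection.

## The Markov-assumption simulation

If attribute dependence along a chain is first-order (each recruit's
value depends only on their recruiter's), correlation at tree distance
*d* must decay geometrically as ρ<sup>d</sup>. `simulate_ar1_on_forest()`
makes this testable on the *observed* topology: per replicate, seeds draw
standard normal values and each child is ρ·parent + √(1−ρ²)·noise, which
preserves the standard-normal marginal at every depth (checked by a
pooled Kolmogorov–Smirnov test in the suite). The per-distance
correlation distribution across replicates — median and central 95%
envelope, 2.5–97.5% replicate quantiles — forms the null band to compare
with an observed profile. The envelope is distribution-based rather than
parametric because the per-distance pair counts are small and mutually
dependent on a fixed tree.

## The synthetic generator: what it emulates, and what not

`simulation_config()` defaults encode the motivating pilot survey's
conditions:

| parameter | default | rationale |
|---|---|---|
| `n_seeds` | 80 | completed seed questionnaires |
| `coupons` | 4 | coupons handed to every respondent |
| `participation_prob` | 0.16 | 140 completed recruits from 4 × 220 completers' coupons |
| `max_waves` | 6 | deepest observed chain |
| `rho` (age) | 0.555 | observed recruiter–recruit age correlation |
| `age_mean`, `age_sd` | 26.7, 6.73 | observed age distribution |
| gender stationary / copy | 0.616/0.384, 0.205 | observed shares and phi |
| education stationary / copy | 0.161/0.630/0.209, 0.52 | observed shares and rank correlation |
| `nb_mu`, `nb_k` | 88.2, 0.57 | fitted degree law |
| `symptom_rate` | 1.8 | mean symptoms per respondent |

Recruitment is a branching process: every completed node issues
`coupons` invitations, each independently completed with
`participation_prob`, truncated at `max_waves`. The effective
participation probability folds the respondents who never invited anyone
into the per-coupon completion rate, which reproduces the observed
sample size (~220 from 80 seeds) without modelling the invite/no-invite
decision separately. Categorical traits follow a **copy-or-draw** kernel
along edges — with probability λ the recruit copies the recruiter,
otherwise a fresh draw from the stationary distribution. This is the
simplest Markov-on-tree kernel, its lag-1 correlation equals λ under any
numeric coding (the kernel is λI + (1−λ)1π'), and seeds draw from the
stationary law so the marginal is wave-invariant. Degree is drawn
independently of topology by default, matching the observed random
mixing by degree; `degree_rho` switches on a latent Gaussian AR(1)
copula for sensitivity studies. Degree is split over the 11 diary
settings by a per-respondent Dirichlet composition whose means reflect a
student diary (≈30% of contacts while travelling); contacts while eating
are negative binomial with mean 10 and dispersion 1 split over four
meals, household sizes follow the observed size distribution with an
open-ended 7+ class, and each of eight named symptoms is an independent
Bernoulli draw with overall mean `symptom_rate`.

What the generator deliberately does **not** emulate: repeated
recruitment and coupon collisions (every pid is unique by construction),
non-response and partial completion (all generated rows are completers),
the unobserved full contact network behind the trees, attribute-dependent
participation, and temporal dynamics of recruitment. Consequently,
passing recovery tests show that the *estimators* are correct under the
stated generative assumptions — they do not certify robustness to the
messiness of real survey data, which is why the deposited-data checks are
kept as separate tests that activate when the real table is present.

## Numerical choices

* **Negative binomial fit** (`fit_negative_binomial()`): (μ, k)
  parameterisation with Var = μ + μ²/k; optimisation of the
  log-likelihood in (log μ, log k) by BFGS from moment starts, with a
  coarse grid over log k as fallback; standard errors by inverting the
  observed information with a delta-method transform back to (μ, k).
  The MLE of μ equals the sample mean for any fixed k, and the optimiser
  must reproduce that identity to 1e-6 in the tests. Underdispersed input
  (variance ≤ mean) triggers a warning and pins k at an upper bound
  (default 1e4), where only the mean is profiled. Censored observations
  at the cap are treated as exact by default — the convention the
  censoring rule implies for its reference analysis — while
  `censored_at` enables the proper right-censored likelihood, which
  shifts mass above the cap (a test asserts the direction of that
  shift).
* **Tie and ordering conventions**: components labelled by smallest pid;
  recruitment order wave-major then pid; education levels ordered
  below-bachelor < bachelor < master-or-higher when supplied as strings.
* **Degenerate inputs**: all-equal degrees are rejected (k unbounded);
  zero-variance pair margins raise an undefined-correlation error, which
  distance profiles convert to `NA` rows; all-singleton components pin
  σ²<sub>u0</sub> to the boundary (ICC 0); a lone component is rejected.
* **Orphan recruiter references** default to a hard error; a lenient
  flag demotes orphans to seeds with a warning, surfacing data problems
  loudly rather than silently repairing them.

## Problem sizes in the test suite

The suite validates statistical behaviour at sizes chosen to keep Monte
Carlo error informative: parameter recovery of the degree law at
n = 5000; six replicate synthetic surveys of ≈5500 respondents for
end-to-end recovery of (ρ, copy probabilities, μ, k) within three
Monte-Carlo standard errors; the AR(1) decay check on a deep chain forest
with 2000 replicates; the BFS pair-enumeration oracle on 100 random
forests; and balanced variance-component designs of 200 components × 5.
Branching configurations in tests are kept subcritical or depth-capped so
component sizes — and hence the quadratic cost of all-pairs enumeration —
stay bounded.

## Known limitations

Confidence intervals for pair correlations ignore the dependence between
pairs sharing individuals; the Fisher-z intervals are approximate and the
simulation envelope is the preferred reference. The Salganik–Heckathorn
(RDS-I) estimator and bootstrap variance estimation for RDS estimates are
out of scope, as is Newman's degree-assortativity coefficient on the full
(unobserved) contact network — all analyses concern recruitment-tree
pairs only. The generator's participation model is memoryless and
homogeneous; real recruitment shows seed effects and channel effects that
the package summarises (`recruitment_summary()`) but does not simulate.
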