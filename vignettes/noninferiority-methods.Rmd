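---
title: "Bayesian noninferiority analysis and cost-minimisation for cluster-randomised implementation trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian noninferiority analysis and cost-minimisation for cluster-randomised implementation trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

School physical activity policies only pay off at scale, and the
implementation support that makes schools follow them (training workshops,
in-school champions, ongoing consultation) is expensive when delivered in
person. A natural optimisation question is whether a cheaper delivery model
— replacing in-person contact with remote, champion-led modes — is *as good
as* the original. That is a noninferiority question, not a superiority one:
the adapted model wins if it loses at most a pre-specified margin of the
original model's effect while costing less.

`niclust` implements the full analytic pipeline for such a two-arm,
school-randomised noninferiority trial in which teachers record their
scheduled weekly minutes of physical activity (PE, sport, energisers,
active lessons) in logbooks at baseline and 12-month follow-up:

1. a synthetic-trial generator emulating the logbook data structure;
2. ingest and validity filtering of logbook CSVs;
3. derivation of the noninferiority margin and its decision rule;
4. a Bayesian baseline-adjusted linear mixed model for total weekly
   minutes, with one-step posterior-predictive imputation of missing
   outcomes;
5. longitudinal gamma-hurdle models for the component outcomes;
6. posterior summaries: probability of noninferiority and a
   posterior-predictive variance ratio (a Bayesian analogue of the ICC);
7. a bootstrap cost-minimisation from the provider perspective.

## The noninferiority margin

The margin is derived from the reference trial that established the
original support model. If that trial's effect had lower 95% confidence
bound $L$ and the decision panel requires a proportion $p$ of the effect to
be retained, then

$$\Delta = -(1 - p)\, L .$$

With the conventional $p = 0.5$ and $L = 32.8$ minutes/week this gives
$\Delta = -16.4$ minutes/week: the adapted model is noninferior if it
delivers no more than 16.4 weekly minutes less than the original. Component
outcomes carry their own pre-specified margins (−8.25 energisers, −1.58
active lessons, −0.95 PE). Two decision summaries are reported side by
side and never collapsed into each other:

* the **interval rule** — noninferior if the lower bound of the 95%
  equal-tailed credible interval for the between-arm difference does not
  cross $\Delta$ (a bound exactly at $\Delta$ counts as non-crossing, taking
  "does not cross" literally);
* the **posterior probability** $\Pr(\beta \ge \Delta \mid \text{data})$,
  the fraction of posterior draws on the non-inferior side.

These answer different questions (a binary decision at a fixed error rate
versus a graded evidence summary); reporting both mirrors how such trials
are read in practice.

## The primary-outcome model

Total weekly minutes at follow-up are modelled as

$$y_{ij} = \alpha + \beta\,\text{arm}_j + \gamma\, b_{ij} + u_j +
\varepsilon_{ij}, \qquad u_j \sim N(0, \sigma_u^2), \quad
\varepsilon_{ij} \sim N(0, \sigma_e^2),$$

for teacher $i$ in school $j$, with baseline total $b_{ij}$ and a school
random intercept to absorb the cluster randomisation. $\beta$ (adapted
minus original, minutes/week) is the noninferiority contrast. Baselines get
their own sub-model $b_{ij} \sim N(\mu_b, \sigma_b^2)$ so that missing
baselines and follow-ups are *jointly* imputed: each missing outcome is a
stochastic node drawn from its posterior predictive distribution at every
MCMC iteration (the one-step approach). This propagates imputation
uncertainty into $\beta$ exactly; with no missing data the machinery is
inert and the fit is identical to a complete-data fit.

Uninformative priors are vague on the minutes scale: $N(0, 100^2)$ on
location parameters, Half-Normal(0, 50) on the SDs. An informative mode
accepts user-supplied Normal hyperparameters for $\beta$ (for example from
the reference trial); no informative defaults are invented. With trial-size
data the two modes give practically identical results — a property the test
suite checks.

Sampling is delegated to JAGS (Gibbs/slice kernels) through `rjags`. The
model is *hierarchically centred* — school means
$m_j \sim N(\alpha_c + \beta\,\text{arm}_j, \sigma_u^2)$ — and the baseline
covariate is centred at its observed mean. Both choices are purely
computational: they remove the ridge between the intercept, the school
effects and the baseline slope that traps Gibbs samplers when $\sigma_e$ is
small, and they noticeably improve mixing at trial scale. Initial values
are data-based (moment estimates, jittered per chain). The default run
configuration is 4 chains with 10,000 burn-in and 10,000 retained
iterations each; examples and tests use shorter runs.

## The component-outcome models

Component minutes have a point mass at zero (many teachers schedule no
energisers in a given week) and a right-skewed positive part, so a linear
model fits poorly. Each component gets a two-part gamma-hurdle model on the
observed records:

* zero part: $\text{logit}\, \Pr(y > 0) = a_0 + a_t t + a_g g + a_{tg} tg +
  u^z_j$;
* positive part: $y \mid y>0 \sim \text{Gamma}(k, k/\mu)$ with
  $\log \mu = b_0 + b_t t + b_g g + b_{tg} tg + u^p_j$,

with time $t$, arm $g$, and independent school random intercepts in each
part (sharing one intercept across link scales would be a stronger
assumption than the data warrant). This longitudinal form uses complete
cases only — no imputation — because imputation within the hurdle
likelihood is fragile; the baseline-adjusted form is reserved for the
primary outcome. Link-scale priors are $N(0, 10^2)$ for coefficients and
Half-Normal(0, 2) for the random-intercept SDs: a logit or log coefficient
of ±10 is already far beyond anything observable, and minutes-scale-vague
priors like $N(0, 100^2)$ cause overflow through the exponential links.
The gamma shape takes Half-Normal(0, 10).

The headline component estimate is the exponentiated positive-part
interaction $e^{b_{tg}}$: the ratio-scale between-group difference in the
change from baseline to follow-up. Because the component margins are stated
in minutes, `hurdle_minutes_difference()` also maps every posterior draw to
the expected minutes $E[y] = \Pr(y>0)\,\mu$ at the four arm-by-time design
points (random intercepts at zero) and forms the difference-in-differences;
the probability of noninferiority for components is computed from those
minutes-scale draws. This mapping is this package's explicit construction —
margins on the minutes scale cannot be compared to ratio-scale estimates
without one.

## Posterior summaries

`summarize_difference()` reports the posterior mean and the equal-tailed
2.5–97.5 percentile interval (the standard convention in trial reporting;
highest-density intervals would differ only for skewed posteriors).

The **variance ratio** expresses how much of the posterior-predictive
outcome variance is attributable to clustering. Per posterior draw, the
package simulates predictive deviations over the observed design twice with
common random numbers: once on the residual scale only (conditioning on the
random effects) and once adding freshly drawn school intercepts (not
conditioning), then reports $(V_m - V_c)/V_m$, summarised by its posterior
mean and 95% interval. For the linear model this estimates
$\sigma_u^2/(\sigma_u^2+\sigma_e^2)$; the finite-school simulation is
deliberate, since it reproduces the reporting convention in which weak
clustering yields interval bounds below zero. Common random numbers
guarantee the ratio is exactly zero when the clustering SD is zero.

Convergence is watched with the classic Gelman–Rubin potential scale
reduction factor (floored at 1; the raw pooled-variance ratio dips
marginally below 1 when between-chain variance vanishes) and an
autocorrelation-based effective sample size using Geyer's initial monotone
positive sequence, combined across chains and capped at the total draw
count. Runs with any $\hat R > 1.05$ or ESS $< 400$ trip a prominent
warning — results are still produced, since the thresholds are a reporting
gate, not a published rule.

## The synthetic-trial generator

No trial data are deposited, so the generator is a first-class module: it
emulates 24 schools per arm randomised within region-by-geolocation strata,
3–8 teachers per school, baseline totals $N(126, 46^2)$, follow-up totals
from the linear model above (defaults: slope 0.35, arm effect −7.5, school
SD 16, residual SD 33, original-arm follow-up mean 164), and per-component
hurdles calibrated so that component means and SDs at both timepoints look
like real logbook summaries (energisers rising steeply by follow-up, active
lessons rare and small, PE near-universal). Defaults were calibrated once to
the descriptive statistics of the motivating trial and are not tuned
thereafter.

Totals and components must coexist: the trial analyses totals as Normal and
components as hurdles, and the total must equal the sum of its components
on every record. The generator reconciles the two by letting the sport/other
remainder absorb the gap between the Normal total draw and the component
sum; on the minority of records where the components alone exceed the
total, the components are rescaled so the total is preserved exactly. The
cost of this choice is a small downward bias in component marginal means
under headroom-poor scenarios, which is why hurdle-specific tests simulate
component records directly. Minutes are recorded at 2-decimal precision, as
a logbook would hold them, which also makes CSV round-trips exact.

Missingness is injected completely at random (defaults 5% baseline, 30%
follow-up, matching realistic teacher dropout); nothing in the imputation
model conditions on more than arm and baseline, so MCAR is the weakest
consistent mechanism. Invalid records emulate schools whose logbook process
broke down: a school is selected with probability 0.125 and *all* its
follow-up records are inflated past the 250-minute validity cap, so the
school leaves the analysed tally exactly as such schools leave a trial's
flow diagram.

## The validity filter and a limitation worth knowing

Records claiming more than 250 minutes across the five-day school week are
implausible and excluded ("no more than 250" is read inclusively — exactly
250 is valid; the threshold and inclusivity are configurable because
trial documents are not always consistent on the boundary). Teachers, not
schools, are the exclusion unit; a school drops out only when none of its
teachers contributes valid data.

One property of this rule deserves emphasis: applied to outcomes whose
legitimate distribution has mass above the threshold, the filter truncates
the upper tail — and truncates the higher-mean arm more. Under the default
synthetic scenario this attenuates the fitted arm contrast by roughly one
minute. It is a property of the validity rule itself, not of the estimator:
the package's interval-calibration checks (credible-interval coverage,
probability-of-noninferiority calibration at the margin) therefore run on
unfiltered datasets, where the data-generating effect is the estimand. Users
analysing real data should be aware that a hard validity cap close to the
bulk of the data shades baseline-adjusted contrasts toward zero.

## Cost-minimisation

Noninferiority licenses a pure cost comparison. Cost items are
strategy-coded ledger rows in 2019 Australian dollars (research and
development costs are excluded by never being ledger items); arm-level
"shared" items are apportioned equally across the arm's schools. Point
estimates are per-arm totals and per-school means (rounded to whole dollars
for reporting only), with original-minus-adapted differences. Uncertainty
comes from a non-parametric bootstrap (default 1000 replications) that
resamples *schools* within arm — the school is the costing unit, so it is
the natural resampling unit. Scale-up projections multiply the per-school
saving by a target school count and are lower bounds when the target is a
"400+"-style floor. Two distinct percentages are computed and labelled:
the per-school cost reduction $100(c_o - c_a)/c_o$ and the
schools-per-budget increase $100(c_o/c_a - 1)$; they are often conflated
in prose but differ (35% versus 55% at the packaged ledger's values).

The packaged ledger (`example_ledger_path()`) is a synthetic reconstruction:
per-school strategy costs with a fixed zero-sum spread plus a per-arm
shared balancing item, chosen so the arm totals are exact. Printed
strategy-level costs rarely sum to programme totals (salaries and
distribution are typically not itemised per school); the balancing item
makes that gap explicit rather than hiding it.

## Problem sizes used in the checks

The package's acceptance checks run at deliberately chosen sizes: conjugate
sampler oracles at 4 chains × 4,000 draws; 100 replicate synthetic trials
at 24 schools/arm with 4 × 1,000-draw chains for coverage and calibration;
a single hurdle fit at 20 schools × 8 teachers for the marginal-mean
identity; bootstrap intervals at 1,000 replications against a
100,000-replication reference; and two full pipeline runs for byte-level
determinism. These sizes make the Monte-Carlo yardsticks (3 Monte-Carlo
SEs, binomial coverage bands) meaningful while keeping a full run of the
suite practical on a single CPU.

## Known limitations

* The generator models teacher dropout as MCAR and has no teacher-level
  covariate effects; informative missingness would require a different
  imputation model than the trial pre-specified.
* The hurdle models use observed records only; if missingness correlated
  with component scheduling, their contrasts could be biased in ways the
  primary outcome's imputation model avoids.
* The variance-ratio convention is simulation-based by design; its interval
  width partly reflects the finite number of schools, which is what makes
  negative lower bounds possible.
* The mapping from ratio-scale hurdle estimates to minutes-scale margins is
  a modelling construction (random intercepts at zero); other choices
  (averaging over the fitted intercepts) would shift component
  noninferiority probabilities somewhat.
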