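---
title: "Estimating and projecting twinning rates by maternal age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and projecting twinning rates by maternal age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinprop)
```

## The problem

Twinning — delivering two children at one birth — is rare (roughly 5 to 30
per 1000 deliveries across populations) and rises with maternal age,
peaking in the late thirties before declining slightly. At the population
level, two demographic forces therefore shape the future of twin births in
countries where medically assisted reproduction remains uncommon: the shift
of childbearing toward older ages, which raises the twinning *rate*, and
the change in the total number of births, which scales the *count* of twin
births. `twinprop` estimates the individual-level age–twinning relationship
from retrospective birth histories and propagates it, with uncertainty, onto
projected maternal age structures.

Throughout, the analysis unit is the **delivery**: a single birth event
producing one child (singleton) or two (twin). All multiple births are
treated as twins — higher-order multiples are a negligible share of
multiple deliveries in the populations emulated here — and the twinning
rate `tr` is twin deliveries per 1000 deliveries (the per-delivery fraction
in formulas).

## The propensity model

On delivery-level data, `twin_lpm()` fits by ordinary least squares

$$\mathrm{twin}_{i,c} = \beta_{a(i)} + \gamma_c + \varepsilon_{i,c},$$

with maternal-age-category dummies $\beta_a$ (5-year categories 15–19 …
45–49 by default; 1- and 2-year schemes as robustness options, reference =
youngest category, fixed at 0) and country fixed effects $\gamma_c$ that
absorb the global intercept. The linear probability model is preferred to
logistic regression because for very rare outcomes its predicted
probabilities track the observed distribution closely, and its coefficients
are directly interpretable as probability differences, which is what the
projection consumes.

Choices a user should know about:

* **Covariance.** LPM errors are inherently heteroskedastic, so the default
  coefficient covariance is the HC1 sandwich estimator; classical and
  mother-clustered covariances are available via `vcov_type`. Clustering by
  mother is optional because within-mother deliveries are modelled as
  independent by default (see the generator section).
* **Age and parity.** Parity is carried on records but deliberately not
  included in the design: population projections tabulate births by maternal
  age only, so the age coefficients are meant to absorb the combined
  age-and-parity gradient.
* **Year terms.** The default design has no year terms — country effects are
  treated as stable over the (10-year) observation window. `year_effects =
  TRUE` adds birth-year dummies for sensitivity.
* **Out-of-range fits.** Fitted values may fall outside $[0,1]$; they are
  stored unclipped and clipped only where consumed as probabilities.

`fit_country_rates()` fits the age-free companion model (country indicators
only), whose per-country point estimate is exactly the observed twin
fraction; its sampling variance is $p(1-p)/n$, the robust variance of a
per-country mean.

**Posterior draws.** `draw_posterior()` draws parameters from a multivariate
normal centred at the OLS estimates with the fit's covariance — the
flat-prior Bayesian posterior of the LPM, which coincides with the OLS
sampling distribution. This is exactly reproducible from a seed and needs
no sampler. A numerically non-PSD sandwich covariance is repaired by
clipping negative eigenvalues at zero (the maximum adjustment is reported).
`fit_per_country()` plus `meta_analyze()` provide the per-country robustness
route: country-by-country age coefficients pooled by inverse-variance
random-effects meta-analysis (DerSimonian–Laird heterogeneity), chosen over
fixed-effects as the conservative default given real between-country
heterogeneity in twinning.

## Data preparation

`read_birth_records()` reads the child-level CSV schema and rejects rows
violating the record invariants (maternal age outside [10, 55], birth after
interview), reporting line numbers. `apply_recall_window()` keeps births
within 10 years of the interview (recall of multiple births is reliable, but
distant singletons may be under-reported, so a symmetric window is safer);
`apply_exclusions()` removes configured countries or country-period subsets
(e.g. populations with early uptake of assisted reproduction), where
"births after year y" excludes years strictly greater than y.
`collapse_to_deliveries()` merges children sharing (country, mother, birth
month) into one delivery; a delivery is twin if it has ≥2 children *or* any
child carries the multiple-birth flag, so a flagged child whose co-twin died
before listing still marks a twin delivery. Ages below 15 or above 49 are
clamped into the edge categories rather than dropped: the 15–49 framing
reflects survey eligibility, not birth-level truncation.

## The country–period panel

`group_years()` builds country × period cells by greedy forward accumulation
of consecutive birth years until each cell holds ≥4000 deliveries, merging
an undersized trailing group backward. Greedy-forward grouping is one of
several ways to "combine adjacent years"; it is used because it is
deterministic and reproducible. The 4000 minimum guarantees about 60–80
expected twin deliveries at rates of 15–20 per 1000
(`check_min_group_rule()` reports the expected count and the exact binomial
probability of at least 50). Countries observed for under 10 years are
removed (`filter_short_span()`) to balance the panel. `fit_panel_fe()` then
regresses the period twinning rate on categories of mean maternal age at
birth (<26, 26–26.5, 26.5–27, 27+; half-open bins with ties upward so the
bins partition the line) with country and period fixed effects, the periods
being 5-year groups with pooled tails (before 1980, after 2015) to smooth
yearly noise. Cells are equally weighted — the presentation mirrors an
unweighted panel OLS — with a delivery-count weight option; classical SEs
are the default presentation with a cluster-by-country option. Optional
GDP-per-capita and primary-education controls enter linearly and
untransformed.

## Projection

From total births $b$ and twinning rate $tr$: $b = d + dt$, $tr = dt/d$,
hence $d = b/(1+tr)$. Per posterior draw, `run_scenario()`

1. converts the flag-selected births (scenario or baseline) to deliveries
   with that draw's $tr$;
2. partitions deliveries by the flag-selected age shares (fractional counts
   are kept; rounding only at display);
3. applies the draw's age-specific probabilities $\gamma_c + \beta_a$ to get
   twin deliveries by age group, their total, and the implied rate;
4. forms percent changes against the baseline inputs under the *same* draw,
   then summarises across draws as median and Q1–Q3.

The same draw index is used for $tr$, $\gamma_c$ and $\beta_a$ so that
parameter uncertainty propagates jointly. Percent changes are computed per
draw before summarising, because for skewed posteriors the change of
medians is not the median change.

**Closure between the two fits.** The age-free rate $tr$ (used in
$d = b/(1+tr)$) and the age-specific profile $\gamma_c + \beta_a$ (used for
$dt$) come from separate regressions, so their baseline-weighted mean need
not equal $tr$ exactly. In the default `"recentered"` mode each draw's
profile is shifted by a constant so its baseline-share-weighted mean equals
the same draw's $tr$; the shift is *iterated* with clipping into $[0,1]$
(tolerance $10^{-12}$, at most 100 iterations) because a single shift
followed by clipping can leave a residual gap when low draws clip at zero.
This guarantees, draw by draw, that the identity scenario reproduces the
baseline exactly and that $b = d + dt$ holds at baseline to floating-point
accuracy. `"raw"` mode applies the unreconciled profile for sensitivity.

The "1 out of every N children has a twin sibling" metric is
$(1+tr)/(2\,tr)$ — the reciprocal of the share of children who are members
of a twin pair, assuming two children per twin delivery.

**Decomposition.** `decompose_change()` attributes the projected change to
its demographic sources by counterfactual substitution. Age shares are
rebuilt from women counts $W_a$ and age-specific fertility rates
$\mathrm{ASFR}_a$ as $s_a \propto W_a \cdot \mathrm{ASFR}_a$; substituting
scenario values factor by factor yields the contribution of fertility
timing (ASFR) versus female age composition to the rate change, and of
population scale ($b$), composition and ASFR to the count change. Because
substitution contributions depend on order, three renderings are reported,
each summing exactly to the total: sequential (a fixed order),
Shapley-symmetrised (averaged over all orders), and one-at-a-time main
effects with the interaction as an explicitly separate term. The exact
decomposition used in published supplementary tables of this literature is
rarely spelled out; counterfactual substitution with explicit interaction
reporting is this package's own choice of rendering.

## The synthetic-data generator

`generate_birth_histories()` emulates the features of pooled DHS/WFS birth
histories that the estimator relies on: per-country baseline twin
probabilities (defaults spanning 0.0069–0.0263, the observed low–high range
across low-income countries), an additive age profile rising to +0.010 at
35–39 then declining slightly (matching the "about 0.01 increase in the
late 30s" magnitude reported from such data), a broad high-fertility age
schedule, mothers with one or more births (ages within a mother increase
with birth order), month-resolution dates inside a 10-year recall window,
and exact two-child emission for twin deliveries. Countries are generated
from deterministic per-country sub-streams of one seed, so output is
bit-reproducible. Deliveries are independent within mothers by default —
the within-mother correlation of twinning is not well established in these
data — with a lognormal mother-frailty knob (`frailty_sd`) for sensitivity.
`generate_projection_tables()` produces WPP-like tables that are consistent
by construction (`births = asfr × women`, shares summing to 1), with
per-year schedules (e.g. `shift_schedule()`) to emulate ageing scenarios.

What the generator deliberately does *not* emulate: survey weights,
clustering and stratification (the estimators here do not use them);
mortality and migration in projections (tables are taken as given);
secular trends in the baseline rate within the observation window;
realistic inter-birth spacing (dates and ages are drawn marginally, then
ordered). Passing tests therefore demonstrate correctness of the estimation
and projection machinery under the stated generative model — not that any
particular real-world dataset satisfies that model.

## Problem sizes and numerical choices

The test suite checks oracle equivalence (explicit normal-equations solves)
to 10 significant digits on small instances; point recovery on ~220,000
generated deliveries (all parameters within 3 robust SEs of truth); interval
calibration over 200 replicates of ~36,000 deliveries (95% CI coverage
pooled over parameters within [90%, 99%]); and end-to-end coverage of the
analytic rate-change truth over 100 pipeline replicates of ~24,000
deliveries with 400 draws each. These sizes were chosen so that Monte-Carlo
error is small relative to the tolerances being asserted while the suite
stays comfortably fast on a laptop. Posterior summaries default to 2000
draws, enough for stable medians and quartiles of smooth functionals.

Degenerate inputs are handled explicitly: empty age categories are dropped
from the design with a warning; a single-country fit reparameterises the
intercept as the country effect; countries with zero twins get a point rate
of 0 with degenerate draws; rank-deficient designs beyond these cases stop
with the offending columns named; a twinning rate of zero makes the
twin-sibling ratio infinite with a warning.

## Limitations

* The LPM "posterior" is the flat-prior normal limit; it does not impose
  $[0,1]$ support, which is why probabilities are clipped at consumption
  and the recentering iteration exists.
* Country effects are assumed stable over the estimation window when
  projected decades forward; temporal fluctuation in baseline rates is
  captured only insofar as it widens the sampling distribution.
* The decomposition's interaction term is genuinely unattributable between
  factors; the Shapley rendering spreads it evenly by construction.
* Zygosity is not modelled; the age gradient operates through dizygotic
  twinning, but the data the package targets do not distinguish zygosity.
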