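---
title: "Projecting chronic-disease burden with the illness-death model"
author: "illnessdeath package"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`illnessdeath` projects the burden of an irreversible chronic disease — the
motivating case is type 2 diabetes — in a birth cohort, from three rate
inputs: the incidence $i(a)$ among the healthy, the general (all-cause)
mortality $m(a)$ of the whole population, and the relative mortality
$R(a) = m_1(a)/m_0(a)$ of the diseased versus the non-diseased. Every person
occupies one of three states, *healthy*, *diseased* or *dead*, with
transitions healthy $\to$ diseased at rate $i$, healthy $\to$ dead at rate
$m_0$, and diseased $\to$ dead at rate $m_1$. The disease is irreversible:
there is no transition back to healthy.

The age- and period-specific prevalence $p(t, a)$ of such a condition obeys
a first-order partial differential equation in period and age. None of the
rates in this package carries a calendar-time trend (a deliberate scope
restriction: period effects in incidence are excluded), so along the life
line of a single birth cohort, $t = t_0 + a$, the equation reduces to an
ordinary differential equation in age:

$$\frac{dp}{da} = (1 - p)\left[\, i - m\,\frac{p\,(R - 1)}{1 + p\,(R - 1)} \right],
\qquad p(0) = 0 .$$

The fraction inside the brackets multiplying $m$ is the population
attributable fraction: prevalent cases experience excess mortality, which by
itself *lowers* the prevalence among survivors. Writing the equation in
terms of $(i, m, R)$ rather than $(i, m_0, m_1)$ matters in practice,
because $m$ comes from official life tables and $R$ from cohort or registry
studies, while $m_0$ and $m_1$ are rarely observed directly. The
decomposition
$$m_0 = \frac{m}{1 + p\,(R-1)}, \qquad m_1 = R\, m_0$$
(`decompose_mortality()`) recovers the state-specific hazards from the
solved prevalence, and its inverse
$R = m_1 (1-p) / (m - p\, m_1)$
(`relative_mortality_from_inputs()`) turns published $(m_1, p, m)$
estimates into the relative mortality the solver needs.

## Scenarios and outcome functionals

Two scenarios are contrasted: *business as usual* (BAU), which uses the
calibrated incidence as observed, and an *intervention* scenario (IAT,
increased active travel in the motivating application) in which the
incidence is scaled by $(1-h)$ at every age, where $h$ is the relative risk
reduction. The default effect size is $h = 0.19$ with 95% CI $(0.11, 0.27)$,
the published estimate for an additional 2.5 hours of moderate-intensity
physical activity per week. Disease onset is assumed impossible at or below
an onset age (35 years by default, appropriate for type 2 diabetes), and the
cohort's birth year (1985 by default) is pure metadata since no rate depends
on calendar time.

From the solved prevalence paths, three outcome families are computed
(`scenario_contrast()` runs them all):

* **Lifetime risk.** $P(a) = \int_0^a i(\tau)
  \exp\left(-\int_0^\tau (i + m_0)\,du\right) d\tau$, the probability of
  contracting the disease before age $a$ with death while healthy as the
  competing risk. The $m_0$ inside uses the scenario's own prevalence
  through the back-formula above, so it differs slightly between scenarios
  while $m$ is shared. The absolute risk reduction is the pointwise
  difference of the BAU and intervention curves.
* **Prevented cases.** With $S(a) = \exp(-\int_0^a m\,du)$ the shared
  survival function, the case count is
  $C = N_0 \int i\,(1 - p)\,S\,d\tau$ and the prevented cases are the
  single integral of the difference of the two integrands. The prevented
  fraction is $\Delta C / C_{BAU}$.
* **Disease-free life expectancy.** Sullivan's estimator
  $e_{DF}(a) = S(a)^{-1} \int_a^{\infty} (1 - p)\,S\,du$, evaluated at the
  onset age for both scenarios; the gain is their difference, also reported
  relative to the BAU value.

## Calibration against a reference population

Cohort studies typically cover a limited age range, so the package follows a
shape-preserving extrapolation strategy: a reference population supplies the
*shape* of the age courses — registry data motivate a **log-parabolic**
incidence, $\log i(a) = c_0 + c_1 a + c_2 a^2$ with $c_2 < 0$, and a
**log-linear**, declining relative mortality, $\log R(a) = d_0 + d_1 a$ with
$d_1 < 0$ — while the target population supplies anchor observations at a
few ages (60 and 70 by default). Under a proportional-hazards assumption the
two populations differ by age-constant factors, $i_{target} = \beta\,
i_{ref}$ and $R_{target} = \gamma\, R_{ref}$, i.e. a vertical offset in log
scale. `fit_log_parabola_offset()` / `fit_log_line_offset()` estimate that
offset as the mean log-ratio over the anchors (the least-squares solution;
with one anchor the fit is exact through that point), leaving the curvature
untouched. The relative mortality may fall below 1 at high ages if the
fitted log-line implies it; the solver warns but applies no floor, since the
shape assumption, not a constraint, is the model.

## Uncertainty propagation

Input uncertainty is propagated by Monte-Carlo resampling
(`run_resampling()`): in each of $K$ replicates (5000 by default) and for
each sex, the anchor observations $(i, m_1, p)$ are perturbed, the relative
mortality is back-calculated, the offsets are refitted, an effect size $h$
is drawn from its normal distribution truncated to $[0, 1)$, and the whole
pipeline is rerun for both scenarios. The distribution of the replicate
outcomes reflects the combined input uncertainty.

Decisions taken where the procedure was underdetermined:

* The sampling distribution of the anchors is **log-normal** around the
  observed values with configurable log-scale SD (default 0.1) —
  positivity-preserving and the natural noise model for rates.
* The BCa interval (`bca_interval()`) is applied **directly to the $K$
  Monte-Carlo outcome replicates**, with the unperturbed point-estimate run
  as the reference estimate for the bias correction; the acceleration
  constant comes from the jackknife (leave-one-out means) of the replicate
  sample. This reads the replicate distribution as the resample
  distribution; Monte-Carlo drawings and bootstrap replicates are therefore
  separate, independently configurable counts.
* One master seed draws per-replicate seeds up front, so increasing $K$
  extends the replicate sequence without reshuffling earlier replicates,
  and a replicate whose perturbed inputs are epidemiologically inconsistent
  (e.g. $m - p\,m_1 \le 0$) is logged and redrawn with a deterministic
  follow-up seed.
* Replicate-level sanity (rates positive, $p < 1$) is enforced by
  construction and by redraw, not by clamping.

The interval-calibration check in the test suite is scaled down relative to
routine use: 200 synthetic data sets, $K = 500$ replicates each, on a
0.2-year grid — sizes at which Monte-Carlo sampling error, not grid error,
dominates the interval endpoints.

## The synthetic study

Real applications of this pipeline rest on three external sources: anchor
estimates from a cohort study, reference shapes from a disease registry, and
official mortality tables. None of these can be redistributed here, so the
package ships a first-class generator (`synthetic_config()`,
`synthetic_study()`) that emulates their statistical structure:

* reference incidence log-parabola peaking at age 80 at about 1.5% per year
  (male level; the female curve is a constant log-offset below it — sex
  differences enter through the level only, a parsimony choice);
* log-linear relative mortality declining from about 4 at age 35 towards 1
  near age 95 (crossing below 1 afterwards, which the solver flags);
* Gompertz–Makeham general mortality $m(a) = \lambda + \varphi e^{\theta a}$
  with defaults $(5\times10^{-4}, 3\times10^{-5}, 0.095)$ for men and
  $(4\times10^{-4}, 9\times10^{-6}, 0.106)$ for women, giving life
  expectancies of 77.2 and 81.6 years and survival to age 110 below
  $10^{-4}$, so truncating improper integrals at 110 is numerically
  negligible;
* planted calibration factors $\beta = 1.25$, $\gamma = 0.9$ and anchor
  observations at ages 60 and 70 whose noise-free values are **internally
  consistent**: the anchor prevalence is the solved model prevalence under
  the planted rates and $m_1$ comes from the exact decomposition, so with
  zero noise the full pipeline reproduces the planted truth identically.

These defaults place the male lifetime risk by age 90 in the tens of
percent, the regime in which such projections are typically reported. What
the generator does *not* emulate: real anchor estimates are correlated
(shared denominators), incidence data are age-grouped rather than pointwise,
mortality improves across cohorts, and true age courses deviate from exact
log-parabolas/log-lines. Passing tests therefore validate the machinery and
its statistical calibration under the stated noise model, not the realism of
any particular input set.

## Numerical choices

* **Integrator.** Classical fourth-order Runge–Kutta on a fixed age grid,
  implemented in compiled code with rates pre-evaluated at half-step
  resolution. Each solve can self-check by re-solving at half the step and
  requiring agreement within $10^{-6}$ (on by default; turned off inside
  the Monte-Carlo loop, whose grid is validated once).
* **Grid.** Default step 0.05 years on $[0, 110]$. The solver alone is far
  more accurate than $10^{-6}$ already at 0.1, but the trapezoidal outcome
  integrals reach the package's stability contract — all integrals stable
  to better than $10^{-6}$ relative change under grid halving — only at
  0.05; since a full two-scenario, two-sex run takes well under a second,
  the finer grid is the default everywhere.
* **Onset discontinuity.** The onset cutoff makes the incidence jump at the
  onset age. The solver integrates from the onset grid node with $p = 0$
  and evaluates the incidence right-continuously there; disease-related
  quadratures restart accumulation at that node. A naive treatment loses an
  order of accuracy at the straddling panel. The onset age must therefore
  fall on the integration grid (35 does, for any step dividing 5).
* **Degenerate inputs.** $1 + p(R-1) \le 0$ aborts with the offending age;
  negative prevalence beyond $-10^{-12}$ (or above $1 + 10^{-12}$) aborts,
  smaller floating-point dust is clamped; a tabulated schedule evaluated
  outside its grid range is an error rather than an extrapolation —
  extrapolation is reserved for the parametric shapes.
* **Microsimulation tie-break.** The individual-level validator
  (`simulate_cohort()`) uses discrete time steps ($dt \le 0.1$, default
  0.05): within a step, onset and death are drawn independently with
  probabilities $1 - e^{-i\,dt}$ and $1 - e^{-m_0 dt}$, and a simultaneous
  pair is resolved by competing-risk splitting with onset probability
  $i/(i + m_0)$. The discretisation bias is $O(\text{rate}^2 dt)$, well
  below the sampling noise of the $N = 10^5$ cohorts used in the
  equivalence checks (which compare at three standard errors).

## Interfaces

The package is driven from R; there is no shell executable. The exported
surface maps one-to-one onto the pipeline stages — generation
(`synthetic_study()`), calibration (`fit_log_parabola_offset()`,
`fit_log_line_offset()`), solving (`solve_cohort_prevalence()`), outcomes
(`scenario_contrast()`), uncertainty (`run_resampling()`,
`summarize_uncertainty()`), validation (`simulate_cohort()`,
`empirical_outcomes()`) and orchestration (`run_full_analysis()`,
`write_results()`). External inputs use plain formats: `age,rate` CSV
tables, anchor CSVs with columns `age,i,m1,p,m`, and a YAML run
configuration whose shape-coefficient keys are `incidence_logparabola:
[c0, c1, c2]` and `relative_mortality_logline: [d0, d1]`; synthetic and
file-based inputs are interchangeable (a test exports the synthetic study
to files and checks the results are identical).

```{r example}
library(illnessdeath)
bundle <- run_full_analysis(run_config(K = 1000, seed = 1))
print(bundle)
write_results(bundle, "projection-output")
```

## Limitations

* No calendar-period trends: incidence and mortality are frozen at their
  calibrated age courses, which understates intervention benefits if
  incidence is secularly rising, and overstates mortality for later
  cohorts.
* The proportional-hazards calibration transfers the *shape* of the
  reference population exactly; real target populations may differ in
  curvature, not just level.
* Sullivan's estimator assumes the period prevalence applies to the cohort
  — exact here because the prevalence is the cohort's own solution, but a
  caveat when the method is applied to external prevalence tables.
* The BCa interval treats the Monte-Carlo replicates as a resample
  distribution (see above); with strongly asymmetric input uncertainty a
  nested bootstrap would be preferable.
* Only the three-state irreversible model is implemented: no remission, no
  disease subtypes, no type 1 diabetes below the onset age.
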