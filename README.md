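# illnessdeath

Projection of chronic-disease burden in a birth cohort with the
illness-death multistate model, for epidemiologists and health-policy
modellers who want to ask: *if an intervention lowered the incidence of an
irreversible disease by a known relative amount, how many cases would be
prevented, how much would the lifetime risk fall, and how many disease-free
years would be gained?* The motivating application is type 2 diabetes under
an incidence-lowering physical-activity (active travel) policy.

## The model

Each cohort member is *healthy*, *diseased* or *dead*. With incidence
`i(a)`, general mortality `m(a)` and relative mortality `R(a) = m1/m0` of
the diseased versus the non-diseased, the age-specific prevalence `p(a)`
along the cohort's life line satisfies

    dp/da = (1 - p) * [ i - m * p(R - 1) / (1 + p(R - 1)) ],   p(0) = 0,

which the package integrates with a fixed-grid fourth-order Runge-Kutta
scheme (compiled core). From the solved prevalence it computes, per sex and
scenario:

* **lifetime risk** `P(a) = ∫ i exp(-∫ (i + m0))`, with death while healthy
  as the competing risk and `m0 = m / (1 + p(R-1))`;
* **prevented cases** `ΔC = N0 ∫ {i_BAU(1-p_BAU) - i_IAT(1-p_IAT)} S`, with
  `S = exp(-∫ m)` the shared survival function, and the prevented fraction
  `ΔC / C_BAU`;
* **disease-free life expectancy** by Sullivan's method,
  `e_DF(a) = S(a)^-1 ∫_a (1-p) S`, and its gain between scenarios.

Sparse anchor observations of a target population are extrapolated across
the full age range by proportional-hazards calibration against reference
shapes (log-parabolic incidence, log-linear relative mortality), input
uncertainty is propagated by Monte-Carlo resampling of the anchors and of
the intervention effect size (default 0.19, 95% CI 0.11-0.27), and BCa
bootstrap intervals summarise the outcome distributions. An
individual-level stochastic microsimulation of the same three-state model
ships as an independent validator.

## Worked example

The package ships a self-contained synthetic study (documented in the
vignette; labelled synthetic, not estimates from any cohort) so the whole
pipeline runs out of the box:

```r
library(illnessdeath)
bundle <- run_full_analysis(run_config())
print(bundle)
```

```
projection results
==================
scenario contrast (male):
  prevented cases: 5647 of 37145 (15.2%)
  disease-free life expectancy at 35: 36.75 -> 37.92 years (+1.17, +3.2%)
  lifetime risk (%):
  sex age risk_bau risk_iat arr
 male  40      1.5      1.2 0.3
 male  50      6.6      5.4 1.2
 male  60     14.8     12.1 2.6
 male  70     24.5     20.4 4.1
 male  80     32.6     27.5 5.2
 male  90     36.5     30.9 5.6
scenario contrast (female):
  prevented cases: 4784 of 29260 (16.3%)
  disease-free life expectancy at 35: 42.16 -> 43.14 years (+0.98, +2.3%)
  ...
```

Reading the male block: under business as usual, 37,145 of the 100,000
cohort men contract the disease over their lifetime and a man's risk of
onset before age 80 is 32.6%; the intervention (incidence scaled by
1 - 0.19 above the onset age of 35) averts 5,647 of those cases (15.2%),
lowers the age-80 risk by 5.2 percentage points, and adds 1.17 disease-free
years to the 36.75 expected at age 35. Adding `K = 5000` to `run_config()`
attaches 95% BCa intervals to every scalar outcome;
`write_results(bundle, dir)` writes the risk table (CSV), scalar outcomes
and intervals (JSON) and a run manifest with the seed and config hash.

External inputs are supplied with `run_config(input = "files", ...)`:
`age,rate` CSV tables for mortality, anchor CSVs with columns
`age,i,m1,p,m`, and the reference-shape coefficients — the same formats the
synthetic generator writes, so the two are interchangeable.

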