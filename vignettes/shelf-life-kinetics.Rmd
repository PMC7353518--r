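---
title: "Modelling cracker shelf life from ingredient-oil oxidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cracker shelf life from ingredient-oil oxidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shelfkin)
```

## The problem

Packed low-moisture bakery products such as crackers spoil on the market
mainly through lipid oxidation: hydroperoxides formed in the fat break down
into volatiles that the consumer perceives as rancid odor. The oxidative
status of the ingredient oil — measured as its peroxide value (PV, in
milliequivalents of active oxygen per kg of oil) — varies between
deliveries and during in-plant storage, and it propagates into how fast the
finished product turns rancid. shelfkin implements the modelling chain that
turns an accelerated shelf-life study into a quantitative answer to two
production questions: *how long will a cracker batch last given the PV of
the oil it was made with*, and *what is the highest oil PV compatible with
a target shelf life*.

Two empirical facts shape the chain. First, the PV of the finished cracker
is a poor quality indicator: baking chemistry (oxygen exposure during
leavening, Maillard–lipid interactions) decouples the product's
hydroperoxide pool from the ingredient's, and the temperature dependence of
PV growth during storage is not kinetically well behaved. The sensory
intensity of rancid odor, scored by a trained panel, discriminates the
batches cleanly instead. Second, although just-baked crackers smell the
same regardless of oil quality, the *rate* at which rancid odor develops
during storage increases linearly with the oil's PV. The package therefore
models rancid-odor intensity, not product PV; the peroxide-value assay
module exists to characterize the *ingredient* oil.

## The modelling chain

**Zero-order kinetics per temperature.** Rancid-odor intensity $I$ on a
7-point scale (anchor 4 = fresh control) grows linearly with storage time
$t$ at constant temperature:

$$I(t) = I_0 + k\,t$$

`fit_zero_order()` estimates $k$ (intensity/day) by ordinary least squares
on the panel means. Observations flagged *censored* — where the noiseless
trajectory has passed the scale ceiling of 7, so panelists can no longer
express further deterioration — are excluded by default; including them
flattens the apparent rate (see `exclude_censored`). Fitting is unweighted
by default; `weights = "inv_sem2"` weights each panel mean by the inverse
of its squared standard error for markedly heteroskedastic sessions.

**Reparametrized Arrhenius pooling.** The temperature dependence of the
rate is modelled as

$$\ln k = \ln k_{\mathrm{ref}} - \frac{E_a}{R}\left(\frac{1}{T} -
\frac{1}{T_{\mathrm{ref}}}\right),$$

with $T$ in kelvin and $T_{\mathrm{ref}}$ chosen in the middle of the
experimental range (40 °C by default for a 20/40/60 °C design). Centering
at $T_{\mathrm{ref}}$ decorrelates slope and intercept, which matters with
as few as three temperatures. The frequency factor of the classical form
$k = k_0 e^{-E_a/RT}$ is recovered as
$k_0 = \exp(\ln k_{\mathrm{ref}} + E_a/(R\,T_{\mathrm{ref}}))$.
`fit_arrhenius_from_rates()` fits the ln-linear regression to the
per-temperature rate constants (the *two-step* pathway);
`fit_arrhenius_one_step()` fits $I(t,T)$ jointly to all raw observations by
nonlinear least squares with a shared $I_0$, initialized from the two-step
result. On noiseless data the two coincide exactly; on real data the
one-step fit uses every observation instead of compressing each
temperature into a single number first. The package exposes both because
published three-temperature tables (with their $n=3$ ln-scale $R^2$ and
$p$ values near 0.06–0.12) are reproducible from the two-step route, while
the one-step route is statistically preferable when raw trajectories are
available. The gas constant defaults to 8.314 J/(mol·K) and is
configurable (8.31 is also in circulation; the choice moves $E_a$ by less
than 0.05%).

**Rate versus oil quality.** At the market temperature (20 °C) the rate
constants of batches made with oils of increasing PV fall on a straight
line, $k_{20} = a\cdot\mathrm{PV} + b$ (`fit_rate_vs_pv()`). For the
reference cracker study the refit of the published rate table gives
$a = 0.0012$ and $b = 0.009$ at printed rounding. The model records the PV
range it was fitted on (5–25 mEq O~2~/kg oil) and warns when asked to
extrapolate; it refuses predictions at temperatures other than the one it
was fitted at, because no rate-versus-PV line exists there.

**Shelf life.** With a producer-chosen acceptability limit
$I_{\mathrm{lim}}$, primary shelf life follows from the zero-order model:

$$\mathrm{SL} = \frac{I_{\mathrm{lim}} - I_0}{k_{20}}
             = \frac{I_{\mathrm{lim}} - 4.33}{0.0012\cdot\mathrm{PV} + 0.009},$$

where 4.33 is the mean rancid-odor score of just-baked crackers (a free
parameter, `I0`). `predict_shelf_life_from_pv()` evaluates this,
`max_admissible_pv()` inverts it to give the highest acceptable ingredient
PV for a target shelf life, and `shelf_life_surface()` tabulates SL over a
PV × $I_{\mathrm{lim}}$ grid. Days convert to months with a divisor of
30.44 (mean Gregorian month) by default — reported shelf lives in months
depend visibly on this convention.

```{r worked}
fx <- cracker_fixtures()
m20 <- fit_rate_vs_pv(fx$rates[fx$rates$temperature_C == 20, ])
m20
predict_shelf_life_from_pv(m20, oil_pv = c(5, 15), I_lim = 6)
```

A PV increase from 5 to 15 mEq O~2~/kg oil multiplies the rate by about
1.8 and therefore shortens shelf life to ≈55% of its value — "about half",
and independent of the acceptability limit chosen, since
$I_{\mathrm{lim}}$ cancels from the ratio.

## The synthetic-data generator

`simulate_sensory_trajectory()` emulates the sensory side of an
accelerated study: per panelist, a score $I_0 + k(T)\,t +
\mathcal{N}(0,\sigma)$ is rounded to the nearest integer of the 7-point
scale and clamped to $[1, 7]$; the panel mean and SD are reported, and an
observation is flagged censored once the noiseless mean exceeds 7. The
defaults mirror the reference study: storage at 20/40/60 °C, a 30-member
panel, batch ground truths taken from the published rate table
(`default_batch_params()`), and panel noise $\sigma = 1.0$ intensity
units, matching the ≈0.9–1.1 score SDs reported for fresh crackers.
Sampling schedules are denser early at the abuse temperatures (defaults:
0–180 d at 20 °C, 0–60 d at 40 °C, 0–18 d at 60 °C), since heavily
oxidized batches reach the scale ceiling within days at 60 °C. Each
(batch, temperature) trajectory draws from its own RNG stream derived from
the study seed, so a subset simulated alone is bit-identical to the same
subset inside a full study.

The generator also emits ferric-thiocyanate standard-curve data
(`simulate_standard_curve()`); `fit_standard_curve()` and `compute_pv()`
convert absorbance readings to PV via

$$\mathrm{PV} = \frac{(A_s - A_c) - I_c}{m} \cdot
\frac{1}{55.84 \cdot 2 \cdot W_s},$$

i.e. absorbance → µg Fe through the curve (intercept $I_c$, slope $m$),
then µg Fe → mEq O~2~/kg using iron's atomic weight and the 2-electron
equivalence; µg/g equals mg/kg, which is why a sample mass $W_s$ in grams
yields PV per kilogram. The division by $55.84\cdot 2\cdot W_s$ is adopted
on dimensional grounds, consistent with the standard ferric-thiocyanate
protocol for oils.

**What the simulator does not emulate.** Panelist-level correlation across
sessions (each tasting is drawn independently), drift or fatigue of the
panel, between-replicate baking variation, and any mechanistic link
between product PV trajectories and odor. Simulated product-PV curves, if
generated, carry no Arrhenius ground truth — deliberately, since product
PV growth is not kinetically consistent across temperatures. Passing
recovery tests on these simulations therefore demonstrates that the
estimator chain is sound under the model's own assumptions, not that the
zero-order/Arrhenius description is correct for any particular product.

## Numerical and design choices

* **Estimator property tests run on the continuous mechanism.** Rounding a
  $\mathcal{N}(\mu, 0.3)$ score to the integer grid biases the expected
  panel mean by up to $\pm\tfrac{1}{\pi}e^{-2\pi^2\sigma^2}\sin(2\pi\mu)
  \approx \pm 0.05$ intensity units — a quantization artifact that
  oscillates with the fractional part of $\mu$ and would dominate a
  Monte-Carlo bias test without saying anything about the regression
  chain. Parameter-recovery tests therefore disable rounding
  (`round_scores = FALSE`); the default simulation keeps it, as real
  category-scale data have it.
* **Recovery-study problem sizes.** The bias checks use 500 simulated
  studies (3 temperatures × 6 sampling times, observation noise SD 0.3,
  true $E_a$ = 50 kJ/mol, true $k_{20}$ = 0.013/day), with schedules that
  stop more than 3 noise SDs below the scale ceiling — as a sensibly
  designed study would — so clamping cannot bias the panel means.
* **Degenerate inputs.** Fewer than two distinct times or temperatures is
  an error; a perfectly flat trajectory returns $k = 0$ with $R^2$
  reported as 0 and a warning; equal rates at all temperatures give
  $E_a = 0$ with $k_0 = k_{\mathrm{ref}}$; a blank absorbance exceeding
  the sample clamps PV to 0 with a warning.
* **Tie-breaks and conventions.** °C → K adds 273.15 exactly. $p$ values
  are two-sided $t$ tests with $n-2$ df (undefined and reported as `NA`
  for two-point fits). The months divisor, gas constant, reference
  temperature and $I_0$ are all explicit arguments, and the pipeline
  report echoes the values actually used.

## Known limitations

* **Exponential sensitivity of $k_0$.** The frequency factor compounds
  every rounding error in the inputs through an exponential: refitting
  from a rate table printed at 2–3 significant figures reproduces $E_a$ to
  about 1% but can move $k_0$ by tens of percent, and for the highest-PV
  batch of the reference study the published $k_0$ (2.48·10⁸) is not
  consistent with its own published $E_a$ and any rate near the fitted
  $k_{\mathrm{ref}}$ — back-substitution implies $k_{\mathrm{ref}} \approx
  0.042$/day where the rate table gives 0.136–0.162/day. The package
  treats published $k_0$ values as consistency checks, never as
  calibration.
* **Figure-read shelf lives.** Direct evaluation of the combined predictor
  at PV 5 and $I_{\mathrm{lim}} = 6$ gives 111.3 days ≈ 3.7 months; the
  "4 months at PV 5" sometimes quoted from shelf-life surface plots is a
  graphical reading (and depends on the days-per-month convention) and is
  not reproduced by the arithmetic.
* **Validity range.** The rate-versus-PV line rests on three oil batches
  spanning PV 5–25 at 20 °C only. Outside that range, and at any other
  storage temperature, the package extrapolates with a warning or refuses
  outright. The ≈50% shortening from PV 5 to 15 is temperature-independent
  only under the assumption that the PV effect scales the rate
  proportionally at all temperatures, which a 20 °C-only line cannot test.
* **Sensory scale ceiling.** Once a product is judged maximally rancid the
  scale carries no more kinetic information; censoring plus exclusion is a
  pragmatic fix, not a model of the saturated response. Designs should
  sample densely enough before saturation at abuse temperatures.
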