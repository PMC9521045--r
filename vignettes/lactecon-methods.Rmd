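---
title: "Herd lactation curve shape versus 305-day yield as drivers of income over feed cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Herd lactation curve shape versus 305-day yield as drivers of income over feed cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Dairy herds are routinely benchmarked on their average 305-day milk
production (HM305), a single summary of absolute volume. The shape of the
lactation curves behind that volume — how high cows peak, how fast they get
there, how slowly they decline — can be aggregated to annual herd lactation
curve characteristics (HLCC) per parity group. `lactecon` implements a
complete, testable pipeline for asking whether HLCC explains more of the
between-herd variation in income over feed cost (IOFC) than HM305 does:
curve fitting, calendar-year aggregation, economic indicator construction,
a data-editing cascade, linear mixed models with R² decomposition, and
Cox/J non-nested model comparison — driven by a synthetic herd generator
with known ground truth, because the original herd accounting data are
proprietary.

## The lactation curve model

Milk yield at `t` days in milk (DIM) follows the simplified MilkBot curve

$$Y(t) = a\left(1 - \tfrac{1}{2}e^{-t/b}\right)e^{-dt}$$

with magnitude $a$ (kg/day), ramp $b$ (days, reported as *time to peak
yield*), and decay $d$ (1/day). The four-parameter MilkBot family also has
an offset $c$ shifting the start of milk synthesis relative to calving; it
is essentially unidentifiable from monthly test-day records and is fixed at
zero throughout. Useful identities: $Y(0) = a/2$, and post-peak yield
decays exponentially at rate $d$, so

$$P = \frac{\ln 2}{d}$$

is the *persistency* in days — the half-life of post-peak decline. The
constant $\ln 2$ is used at full precision, not its 3-decimal print 0.693.
`b` itself is reported as time to peak yield (the conventional renaming in
this literature), not the argmax of $Y$, which is a function of all three
parameters.

### Fitting

`fit_lactation()` minimises the residual sum of squares over
$a \in (0, 150]$, $b \in (0, 100]$, $d \in [0, 0.05]$ — bounds that bracket
the biological range — starting from $a_0 = 2\max(\text{milk})$ (from
$Y(0)=a/2$), $b_0 = 21$, $d_0 = 0.003$. The optimiser is L-BFGS-B with an
analytic gradient; because the $(a, b)$ profile is a flat curved valley,
the optimiser is restarted from each optimum until the RSS stops improving
(at most 5 restarts), which recovers noise-free parameters to near machine
precision. A second start and a Nelder-Mead fallback guard against
pathological weighing patterns; a fit that still fails carries
`converged = FALSE` with the best parameters found. At least 4 weighings
are required to leave one residual degree of freedom; a lactation is
flagged *complete* when its last weighing is at or beyond 240 DIM
(configurable), a proxy for reaching dry-off.

## Calendar-year aggregation (HLCC)

Lactations do not respect calendar years. Each lactation contributes to
every year it touches with weight proportional to its number of test-day
records in that year: with 5 records in 2008 and 3 in 2009, and `n`, `m`
total records in the herd's cell for those years, it contributes `5/n` to
2008 and `3/m` to 2009. Cells are herd × calendar year × parity group
(primiparous vs multiparous), and the year of a record is the test date's
year, not the calving year — that is what makes the 5-and-3 partition
meaningful. Totals `n`, `m` are counted within a parity group, consistent
with per-parity medians (the alternative — counting across groups — would
make per-group weights not sum to one).

The herd-year HLCC is the **lower weighted median** of the contributing
complete lactations' magnitude, time to peak and persistency: after
normalising weights and sorting by value, the smallest value whose
cumulative weight reaches 0.5. No interpolation is used: the convention is
deterministic, returns an actually observed value, and is directly
checkable against an enumeration oracle. Only complete lactations
contribute, and the first and last calendar year of the recording span are
excluded from herd-level output — lactations touching the span edges are
systematically truncated, so those cells would be biased toward early- or
late-lactation records.

## Economic indicators

From herd-year accounting records (all monetary units EUR):

* **IOFC-cow** = (milk revenue − feed cost) / herd size, where feed cost is
  the sum of concentrates, vitamins, minerals, wet by-products and
  roughage;
* **IOFC-milk** = 100 × (milk revenue − feed cost) / kg milk delivered;
* **herd milk price** = 100 × revenue / kg delivered, and the **relative
  milk price** is its difference from the national raw milk price of the
  same year (the herd's premium for components and quality);
* **equity ratio** = (assets − liabilities) / assets;
* **expansion rate** = relative herd-size growth against the nearest
  available earlier year, divided by the year gap; missing (not zero) when
  no earlier year exists;
* **herd intensity** = kg milk delivered per hectare (delivered rather than
  produced milk is a documented choice; produced milk is not observed in
  accounting data).

The source text describes the herd milk price as kg divided by revenue —
the inverse of a price; this package implements revenue per 100 kg, the
only reading consistent with a price reported in EUR/100 kg.

## Data editing

`apply_filters()` applies, in order: (1) removal of herd-years outside any
run of ≥ 2 consecutive years; (2) removal of organic and direct-selling
herds (their milk prices are not comparable); (3) removal of herd-years
below the 1st herd-size percentile; (4) removal of records outside
per-variable percentile bounds on the listed analysis variables; (5)
removal of records with missing values in those variables. The outlier
cutoffs are not stated in the source literature; the default is outside the
[0.5th, 99.5th] percentiles, exposed in `filter_config()` and never
hard-coded. Percentiles are recomputed on the table as each step sees it
(the stepwise-editing reading); a fixed-at-entry variant would be a one-line
config change. Each step logs excluded and remaining counts, and the audit
arithmetic must reconcile exactly. Re-running the cascade on its own output
is a no-op for the value-based steps; the percentile steps can re-trim (and
that re-trimming can strand an isolated year of a herd), which is inherent
to percentile rules and documented rather than hidden.

## Mixed models

Four linear mixed models: {IOFC-cow, IOFC-milk} × {HLCC set, HM305 set},
each with a forced calendar-year fixed effect (absorbing market-level milk
price swings), a herd random intercept (unobserved management and
environment), and candidate herd covariates (soil type, milking system,
successor, outsourced rearing, equity ratio, herd intensity, relative milk
price, herd size, expansion rate, SCC, calving interval). Continuous
predictors are standardized **before** selection, so coefficients are EUR
per SD and comparable in magnitude. Multicollinearity is screened with
VIFs ($1/(1-R^2_j)$; exact collinearity reported as infinite, not an
error).

Backward selection removes, at each step, the non-forced term whose removal
most decreases the AIC of the maximum-likelihood fit, stopping when no
removal decreases it; ties are broken against the term with the larger Wald
p-value. ML is used inside selection because AIC comparisons across fixed
effect sets are invalid under REML; the selected model is refit by REML for
reporting. p-values are Wald z — a documented choice; with thousands of
herd-years the difference from finite-df corrections is negligible. Note a
consequence of the AIC stopping rule worth knowing: a single pure-noise
candidate survives whenever its likelihood-ratio statistic exceeds 2, which
happens with probability ≈ 0.16 — AIC selection is not consistent, and the
test suite asserts the ~0.84 removal rate rather than a higher one.

Variance explained is decomposed as marginal
$R^2 = \sigma^2_f / (\sigma^2_f + \tau^2 + \sigma^2_e)$ and conditional
$R^2 = (\sigma^2_f + \tau^2) / (\sigma^2_f + \tau^2 + \sigma^2_e)$, with
$\sigma^2_f$ the variance of the fixed-effect predictions, $\tau^2$ the
herd-intercept variance and $\sigma^2_e$ the residual variance. The part
R² of a term group is the drop in marginal R² on refitting without the
group, floored at zero, with the year factor treated as one group — the
most direct reading of "variance explained by a single variable"; no
packaged implementation in the target environment provides it for this
model class.

## Non-nested comparison

The HLCC and HM305 models share controls but neither regressor set contains
the other, so nested likelihood-ratio machinery does not apply. Direction
"A–B" always tests the null *B's regressors cannot improve model A*.

* **J test**: model A is augmented with model B's fitted values as one
  extra covariate; the t/z statistic on that coefficient is the test. In
  `"ols"` mode both models are refit as fixed-effects-only regressions
  (the classical form, with an exact small-fixture oracle); in `"lmm"`
  mode (the pipeline default) the augmentation happens inside A's mixed
  model, with B's fixed-effect predictions as the covariate.
* **Cox test** (Pesaran's operational form, fixed-effects-only refits):
  with $\hat\sigma^2_A = RSS_A/n$, $\hat\sigma^2_{BA} = \hat\sigma^2_A +
  \|M_B\hat y_A\|^2/n$, the estimate is $c = (n/2)\log(\hat\sigma^2_B /
  \hat\sigma^2_{BA})$ with variance $\hat\sigma^2_A\,\hat y_A' M_B M_A M_B
  \hat y_A / \hat\sigma^4_{BA}$. The Cox test is offered only on OLS refits
  because its variance theory is least-squares-specific.

Verdicts: both directions rejected → *no difference* (each model adds
information the other lacks); only one rejected → the model whose null
survived is better; neither → the comparison is uninformative. All
p-values are two-sided normal (t in OLS J mode). Two caveats the tests
encode: the classical asymptotics assume the rival's pseudo-true fit is
non-degenerate (a pure-noise rival with no shared regressors makes the J
statistic under-dispersed — visible in simulation), and both tests are
somewhat liberal at small n. When AIC selection leaves the two models with
identical designs (possible in tiny synthetic runs), the comparison is
degenerate by construction and the pipeline records that instead of
aborting.

## The synthetic world

`generate_population()` emits the four input tables (test days, accounting,
performance, national prices) plus the ground truth that generated them.
What it states, and why:

* **Curve parameters.** Lognormal around parity medians — primiparous
  $a=35$, $b=29.6$, $P=358$; multiparous $a=47.7$, $b=22.1$, $P=240$ —
  which are the published herd-level medians for Dutch herds; herd-level
  and cow-level dispersions are chosen so herd-year HLCC spread matches the
  published SDs to first order.
* **Recording scheme.** First weighing at DIM 5–14, then every 35 ± 7 days
  until a dry-off DIM drawn from 280–420. The 4–6-week interval is an
  assumption (the actual scheme's frequency is not published) and is a
  config field. Milk noise is additive Gaussian, SD 1.5 kg/day, truncated
  at zero — the simplest model consistent with least-squares fitting.
* **Year straddling.** 70% of lactations are placed (late-summer/autumn
  calving) so their weighings cross December 31; the rest calve early and
  dry off within the year. The fraction is a config field and is verified
  empirically to ±5 percentage points.
* **Economics.** IOFC-cow is a known linear model in the standardized
  herd-year covariates (defaults near the published effect sizes, e.g.
  +154 EUR/SD of multiparous herd magnitude, +146 EUR/SD of relative milk
  price), plus year offsets with a dip in the second year (the 2009 milk
  price crisis), a herd intercept (SD 200 EUR) and residual (SD 100 EUR).
  Feed cost is then **derived** as revenue − IOFC·herd size and split into
  five components, so the accounting identity holds by construction and
  parameter recovery is a meaningful test. Delivered milk is 83% of summed
  305-day production — calibrated once so delivered milk per cow present
  is ≈ 7,200 kg/year, which is what the published IOFC-cow/IOFC-milk pair
  jointly implies.
* **HM305** is the herd-year mean of the closed-form 305-day integral of
  each cow's true curve, making the HM305-vs-HLCC collinearity structure
  (magnitude ↔ volume) emerge naturally rather than by fiat.

What it deliberately does **not** emulate: cow identity across years (each
herd-year draws fresh cows; the analysis unit is the herd-year), genetics
and pedigree, within-year seasonality, milk components, and any feedback
from economics to management. A green end-to-end test therefore establishes
that the pipeline recovers a known data-generating process of this
structure — not that real herd data satisfy that structure.

## Numerical and design choices

* Lower weighted median, no interpolation (deterministic, oracle-checkable).
* Completeness threshold 240 DIM, configurable; upstream data would carry
  explicit dry-off flags.
* Curve-fit bounds/starts as above; convergence to RSS changes below 1e-10
  relative, with restart polishing.
* Zero-decay fits have infinite persistency; the pipeline excludes such
  herd-years from modelling (they cannot be standardized) and says so.
* Exact collinearity in VIF → `Inf`, in non-nested augmentation → a
  degenerate-comparison error.
* AIC ties in selection broken by the larger Wald p-value.
* The editing cascade recomputes percentiles per step (config can freeze
  them at entry instead).
* One seed drives everything; rerunning a pipeline config byte-identically
  reproduces every artifact.

## Known limitations

Printed coefficient tables of the source study are not reproducible — the
underlying data are proprietary, and the synthetic world is a structural
stand-in, not a statistical twin. The Cox test is not defined here for
mixed models (OLS refits only), and the in-LMM J test is a natural but
non-classical generalisation. AIC backward selection retains ~16% of
pure-noise candidates by construction. Percentile-based editing is
order-dependent and not idempotent. The empirical claims this vignette
makes (recovery rates, calibration bands, removal probabilities) are
exactly those computed by the test suite; nothing beyond what the tests
measure is asserted.
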