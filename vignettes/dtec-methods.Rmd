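---
title: "Methods: doubling-time energy conversion of tumor-volume trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: doubling-time energy conversion of tumor-volume trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtec)
```

## The problem and the model

Xenograft chemotherapy studies typically report each arm as endpoint
volumes: a tumor grew (or shrank) from $V_I$ to $V_F$ cm³ over a stated
window. `dtec` treats every such segment as exact exponential kinetics, the
standard model for unconstrained tumor growth at these sizes. A phase has a
signed rate constant $r = (\ln V_F - \ln V_I)/t$ (net mitosis minus
apoptosis per cell), a doubling time $t_D = \ln 2/r$ when growing, and a
half-life $t_{1/2} = -\ln 2 / r$ when shrinking. Gompertz or logistic
deceleration is deliberately out of scope: the source data are short
windows over small tumors, where a single exponential phase (or a small
number of them) is the assumption the endpoint format itself encodes.

The analysis rests on the doubling-time energy conversion (DT-EC) map from
kinetics to a per-cell energy,

$$E_G = \ln\!\left[\left(\ln\frac{\ln 2}{t_D}\right)^2\right]\ \text{Emad},
\qquad 1\ \text{Emad} = 23234.59\ \text{MeV},$$

with $t_D$ in seconds. Two readings of the formula's typography are
possible; `growth_energy()` squares the inner logarithm *before* the outer
logarithm. For every biological doubling time $\ln(\ln 2 / t_D) < 0$, so
the alternative (squaring after) would require the logarithm of a negative
number; the adopted reading is the only real-valued one, and it reproduces
the same-energy clustering of the three comparable 840 µg/ml treatments
that the analysis scripts and acceptance tests verify. On this reading the
map is strictly increasing in $t_D$ and invertible on the branch $t_D >
\ln 2 \cdot e$ via `energy_to_doubling_time()`:
$t_D = \ln 2\,\exp(+\sqrt{\exp E_G})$.

Energies are computed and stored in Emad throughout; MeV is applied as a
final presentation conversion so the large constant cannot contaminate
intermediate comparisons. The total tumor energy (histologic grade) scales
the per-cell energy by the inoculated cell count $C_0 h$, and the energy
yield of a regimen is

$$E_{Dose} = \left[E_G^{\text{Treated}} - E_G^{\text{Control}}\right]
\times C_0 h\ \text{Emad}.$$

The endpoint-only trajectories support a regimen-total yield, not a
per-injection decomposition, so $E_{Dose}$ is always the whole-regimen
quantity here.

## The virtual-growth transform

A shrinking arm has no doubling time and the energy map does not apply.
The apoptotic portion is therefore replaced by a *virtual growth* phase of
the same duration. The defining equivalence can be read three ways, all
implemented in `virtualize()`:

* **`half_life_equivalence`** (default): $V'_F = V_I^2/V_F$, which mirrors
  the log-volume change, so the virtual doubling time equals the observed
  half-life exactly. This is adopted as the default because it is the only
  reading under which the virtual growth is "equivalent" to the decay on
  the kinetic scale the rest of the analysis uses, and it is invariant to
  the volume unit.
* **`reflection`**: $V'_F = 2V_I - V_F$, mirroring the absolute volume
  loss.
* **`literal`**: $V'_F = V_I + V_I^2/(V_I - V_F)$, equating the shrink
  fraction with the ratio of initial volume to virtual gain. Note its
  degenerate limit: as the shrinkage vanishes the demanded virtual gain
  diverges (virtual $t_D \to 0$), unlike the other two readings where
  virtual $t_D \to \infty$.

The chosen strategy is recorded in the provenance of every report. Only
four of the fourteen packaged treatments contain shrink phases, so the
choice affects a minority of rows; the default leaves each of their
half-lives numerically intact as virtual doubling times. Multi-phase arms
are aggregated by the time-weighted rate — total virtualized log-volume
change over total duration — which reduces to the single-phase formula for
one phase and matches a whole-arm growth constant for many.

Static phases (no volume change) are rejected as degenerate rather than
assigned infinite doubling time, because the energy map is undefined at
$r = 0$; the pipeline reports such records as per-record failures and
continues with the rest of the cohort.

## Intraday doubling time and regimen efficiency

For fixed window endpoints the doubling time evaluated at elapsed time $t$
is linear in $t$: $t_D(t) = \ln 2 \cdot t /(\ln V_F - \ln V_I)$. A
cell-cycle-specific agent such as docetaxel needs cells to still be
cycling at the next delivery, so an efficient schedule keeps $t_D(t)$ at
each dose delivery at least as large as the relevant waiting interval. The
source account states the comparison interval in two ways, and
`efficiency_profile()` exposes both rather than silently preferring one:
`to_next_dose` (default; the last dose compares to the observation end)
and `from_start`. Reports emit both columns. Boundary equality counts as
efficient (`>=`). A dose at $t = 0$ has $t_D(0) = 0$ by linearity and is
reported as *not evaluable* rather than inefficient, since the criterion
is vacuous there.

By default the evaluation uses whole-trajectory (virtualized) endpoints,
which makes $t_D(t)$ linear and the steadiness check trivially true; a
`scope = "phase"` option evaluates each dose against the endpoints of the
phase containing it, which is sensitive to within-window kinetic changes
(e.g. accelerating regrowth) and can fail the steadiness check.

Schedule classification is a convention, not an inference: a regimen is
*metronomic* when the median inter-dose gap is ≤ 3.5 days **and** the
per-injection dose is ≤ 1 mg/kg, else *standard*. Both thresholds are
arguments. Regimen texts are expanded to explicit injection times from day
0 with uniform spacing where only a rate is stated ("thrice weekly" →
every 7/3 days); the *nominal* dose count implied by the text (rate ×
stated duration, possibly fractional) is kept separately, because the
tabulated µg/ml dose column tracks 28 × cumulative mg/kg of the nominal
schedule in 13 of 14 rows. That factor is an empirical regularity of the
transcribed table, checked at warning level by `audit_dose_column()` and
never used in analysis values; the one inconsistent row (a stated
six-week, twice-weekly schedule whose tabulated dose matches only five
weeks of it) is flagged, not resolved.

## Dose–energy model and prediction

`cluster_identical()` groups energy yields by single linkage under a
relative tolerance, default 5%: the three comparable 840 µg/ml yields
differ by under 1%, so the grouping is insensitive to tolerances in
[0.02, 0.10]. `fit_dose_energy()` is ordinary least squares with an
intercept by default (the through-origin fit is also available and
reported); with cohorts this small only $r$ and $R^2$ are emphasized, and
two-point fits are flagged as underdetermined. `predict_response()` runs
the bookkeeping in reverse — model yield at the proposed dose, added to
the control per-cell energy, inverted through the DT-EC map — and returns
the predicted treated doubling time plus a volume fold-change
$2^{h/t_D}$ over a stated horizon. No claim is made that a fitted model
generalizes across cell lines; the packaged table itself shows same-dose
yields differing by a factor of 30 across models.

## The synthetic-data generator

`simulate_cohort()` emulates exactly the statistical structure the
treatment table assumes: exponential arms summarized by endpoint volumes,
a known inoculum, and energy yields that follow a known linear dose–energy
law. Defaults mirror the packaged dose-840 scale: control doubling time 7
days, inoculum 10⁶ cells, a 24.5-day window, start volume 0.1 cm³, doses
spanning 100–2000 µg/ml, slope 175 Emad/(µg/ml) through the origin.
Measurement noise is multiplicative lognormal on endpoint volumes
(volumes are positive and errors scale with size), with σ configurable;
all randomness flows from one explicit seed through a local RNG state, so
the generator never perturbs the session's random stream. With σ = 0 the
full pipeline returns the generating slope, intercept, per-record yields
and doubling times to numerical precision (the generator/analyzer closure
test); at σ = 0.05 a 20-record cohort recovers the slope within 10%, and
the slope RMSE over 20 replicate seeds decreases monotonically as σ drops
through {0.2, 0.1, 0.05, 0}.

What the generator does *not* emulate: pharmacokinetics, immune response,
inter-animal variability beyond endpoint noise, multi-phase treated arms,
or non-exponential growth. Passing tests therefore certify the
bookkeeping and the estimator under the model's own assumptions, not the
model's fidelity to any particular real tumor.

## Numerical choices and problem sizes

* Doubling times below $\ln 2 \cdot e \approx 1.88$ s are errors (outside
  the invertible branch); values below a configurable plausibility floor
  (default 3600 s) warn but proceed.
* All durations are seconds internally; 1 d = 86,400 s, 1 w = 604,800 s.
* Phase strings round-trip through a canonical day-denominated form at 15
  significant digits; report CSVs serialize numerics at `%.15g` and
  round-trip well beyond 12 significant digits.
* The fixture's transcription is guarded by a frozen md5 checksum.
* Test and analysis problem sizes — 14-row table, 20-record cohorts, 20
  replicate seeds, 2000-point monotonicity grids — keep every stage
  essentially instantaneous while exercising each contract.

## Known limitations

Endpoint-only input means within-window kinetic changes are invisible
unless the source reported phase breaks; the efficiency criterion then
rests on the linear interpolation. The dose–energy model is a two- to
five-point regression in realistic use and should be read as a
consistency summary, not a calibrated dose-finding tool. The Emad unit's
radiobiological motivation is outside this package's scope; it enters
only through the fixed conversion constant.
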