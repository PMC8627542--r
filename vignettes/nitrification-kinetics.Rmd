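---
title: "Estimating nitrification kinetics from incubation time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nitrification kinetics from incubation time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrikin)
```

## The measurement and the model

A potential-rate incubation follows the three dissolved inorganic nitrogen
(DIN) pools — ammonium, nitrite, nitrate — of an aerated slurry over tens of
hours. Nitrification proceeds in two microbially distinct steps: ammonia
oxidation (AO) by ammonia-oxidizing bacteria and archaea, and nitrite
oxidation (NO) by nitrite oxidizers. Because each oxidized molecule of
ammonium passes through the NOₓ⁻ (nitrite + nitrate) pool and every molecule
of oxidized nitrite ends up as nitrate, the *cumulative* activity of the two
guilds is read off two monotone series: NOₓ⁻(t) for AO and NO₃⁻(t) for NO.

Both series typically show a lag phase, an exponential growth phase and a
plateau. `nitrikin` models them with the four-parameter Boltzmann sigmoid

$$y(t) = A_2 + \frac{A_1 - A_2}{1 + e^{(t - t_0)/dt}},$$

the canonical "Boltzmann" form of curve-fitting software: $A_1$ and $A_2$ are
the initial and final asymptotes (µmol L⁻¹), $t_0$ the inflection time (h)
and $dt$ the slope factor (h). Its two virtues here are closed forms for
everything downstream: the curve passes through $(A_1+A_2)/2$ exactly at
$t_0$, and its derivative

$$\frac{dy}{dt} = \frac{(A_2 - A_1)\, e^{u}}{dt\,(1 + e^{u})^2},
  \qquad u = \frac{t - t_0}{dt}$$

is a symmetric bell with maximum $(A_2 - A_1)/(4\,dt)$ at $t_0$. No
alternative sigmoid families (logistic, Gompertz, four-parameter
dose–response) are offered: the package commits to this one form, and model
selection is out of scope.

From a fitted curve the package derives:

* **Average rates** over a window $[T_i, T_f]$ as
  $(y_{fit}(T_f) - y_{fit}(T_i))/(T_f - T_i)$ — fitted endpoint values, not
  raw observations, so the estimate inherits the fit's noise suppression.
  `average_rate_raw()` provides the raw-endpoint variant for comparison.
* **Instantaneous rates** from the analytic derivative; over a window the
  maximum is $(A_2-A_1)/(4\,dt)$ at $t_0$ when $t_0$ lies inside, and the
  derivative at the nearer endpoint otherwise (the derivative is monotone on
  either side of $t_0$, so no grid search is needed).
* **Phase boundaries**: the lag phase ends and the plateau begins where the
  derivative crosses a fraction $f$ of its maximum. Substituting
  $r = e^{u}$ turns the crossing condition into
  $r^2 - (4/f - 2)\,r + 1 = 0$, whose two roots are reciprocal — the
  boundaries sit symmetrically at $t_0 \pm dt \log r$. The default
  $f = 0.10$ is a conventional "10% of maximum activity" cut, exposed as
  `threshold_frac`.
* **The index of nitrogen balance** $INB(t) = DIN(t)/DIN(0)$, computed on
  replicate means. Nitrification conserves DIN, so departures from 1 carry
  information: values below 1 indicate net loss (denitrification, anammox,
  assimilation), values above 1 net gain by organic-matter mineralization.
  The package reports the full trajectory with per-time labels; the last
  element is the classical final/initial index. The balanced band half-width
  defaults to ±0.05, consistent with reading "stable at about 1.0" from
  replicate data with a few percent of measurement noise; it is a reporting
  threshold, not a statistical test, and is exposed as `tolerance`.

The package makes no attempt to attribute nitrogen loss among
denitrification, anammox and assimilation, and performs no formal
between-sample statistics.

## Fitting

`fit_boltzmann()` runs bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with an analytic Jacobian. Starting values come from
the data: $A_1$ from the first observation, $A_2$ from the last, $t_0$ from
the first linear-interpolated crossing of the midpoint (the *first* crossing
is the tie-break when noise makes the series cross several times), and
$dt$ as a tenth of the time span. $A_1$ and $A_2$ are bounded within one data
range of the observed extremes and $dt \in (10^{-6}, \text{span}]$, which
keeps fitted rising series rising over the observation window. Convergence
uses a parameter-step tolerance of $10^{-10}$ and at most 2000 function
evaluations; a non-converged first attempt triggers up to three restarts from
±20% multiplicatively jittered (seed-controlled) starts, and failure after
that raises an error carrying the optimizer diagnostics — a silently
non-converged fit is never returned. Flat series and series with fewer than
five distinct time points (four parameters plus one residual degree of
freedom) are refused up front.

Replicates are averaged before fitting — one curve per sample. Whether each
replicate should instead be fitted separately is a genuinely open choice; the
mean matches the one-curve-per-sample reporting convention and keeps the
per-time SDs available for the optional `1/sd²` weighted fit (off by
default, since no weighting scheme is standard for these incubations).

The driver `analyze_sample()` fits NOₓ⁻ and NO₃⁻, assembles both rate
profiles and the INB series, and names the failing stage in any error. The
window ΔT for average rates defaults to the full sampled span and is
configurable — on sigmoidal series the fitted endpoints flatten onto the
asymptotes, so moderate window changes move V̄ only weakly.

## The simulator: what it emulates and what it does not

`simulate_incubation()` integrates

$$\frac{dNH_4}{dt} = m - v_{ao}, \qquad
  \frac{dNO_2}{dt} = v_{ao} - v_{no} - \lambda\,NO_2, \qquad
  \frac{dNO_3}{dt} = v_{no} - \lambda\,NO_3,$$

with Monod kinetics $v_{ao} = V^{ao}_{max}\,r_{ao}(t)\,NH_4/(K_{ao}+NH_4)$
and $v_{no} = V^{no}_{max}\,r_{no}(t)\,NO_2/(K_{no}+NO_2)$, using
`deSolve::ode` (lsoda, adaptive and stiff-capable, relative tolerance
$10^{-8}$) on a dense grid, then samples at the configured interval and adds
independent additive Gaussian noise per analyte, time and replicate, clipping
negative noisy values at zero. Identical configurations are bit-identical.

Design choices, each deliberate:

* **Induction ramps.** Delayed onset of oxidizer activity is modelled as a
  smooth logistic step $r(t)$ centred at the lag time (width `ramp_*`) rather
  than a hard switch — smoothness keeps the ODE well-behaved and is
  biologically more plausible than an instantaneous on. Both steps can ramp:
  nitrite-oxidizer induction produces transient nitrite accumulation, and an
  ammonia-oxidizer ramp reproduces the sigmoidal (lag-phase) NOₓ⁻ traces seen
  in delayed-regime incubations. A lag of 0 disables the ramp entirely.
* **Loss is applied to NO₂⁻ and NO₃⁻ only**, because the loss pathways it
  stands in for (denitrification, anammox, assimilation of oxidized N)
  consume the oxidized pools; ammonium gains instead a zero-order
  mineralization source. With both set to zero the system conserves DIN
  exactly, which the tests exploit as an oracle.
* **Noise** is additive Gaussian and independent — a deliberate
  simplification standing in for replicate scatter of colorimetric/ion
  measurements.

The simulator returns the noiseless truth (dense trajectories, the true
instantaneous rate curves, and their window averages) alongside the noisy
samples, so recovery of V̄ₐ and the peak rate can be scored against ground
truth rather than against another fit.

What it does **not** emulate: microbial growth (the capacities $V_{max}$ are
fixed apart from the induction ramps, so it cannot produce genuinely
exponential biomass-driven acceleration), spatial or biofilm structure,
temperature and pH dependence, or correlated/heteroscedastic measurement
error. Passing recovery tests on these simulations therefore demonstrates
correctness of the estimators under the stated kinetic model and noise, not
robustness to everything real sludge does.

## Presets

Two presets encode the qualitative regimes the method distinguishes, with
magnitudes chosen to be realistic for anammox-inoculated activated sludge:

* `sample_A_like` — 68 h, sampled every 6 h, 3 replicates, noise SD
  2 µmol L⁻¹; ammonium ~470 µmol L⁻¹; AO induction at 20 h, NO induction at
  27 h with comparable capacities. The delayed NO step lets nitrite build to
  an interior peak of ~104 µmol L⁻¹ near 42 h before being drained, and the
  fitted instantaneous Vₐ exceeds Vₙ early with a crossover once the nitrite
  oxidizers catch up.
* `sample_B_like` — 12 h, sampled hourly (6-hourly sampling over the ~8 h
  active phase would leave too few points to fit), 3 replicates, noise SD
  1 µmol L⁻¹; ammonium 125 µmol L⁻¹ with $K_{ao}$ of the same order, so
  oxidation is near first-order and decelerates from the first hour, and NO
  capacity well above AO so nitrite never accumulates. Fitted rates are
  maximal at the window start and decline throughout — the
  no-nitrite-accumulation regime.

Three diagnostic presets (`closed_system`, `nitrogen_loss`,
`mineralization`) isolate the INB behaviours: conservation at exactly 1,
monotone decline below 1, monotone rise above 1.

## Numerical choices and degenerate inputs

* Derivative evaluation uses $1/(e^{u} + 2 + e^{-u})$, which underflows to 0
  in the far tails instead of overflowing — rates at extreme times are exact
  zeros, never `NaN`.
* The linear (first-order) limit of the simulator, $K \gg$ concentrations,
  is checked against the closed-form two-compartment cascade solution; the
  closed system is checked for DIN conservation to $10^{-6}$ relative.
* Windows must satisfy $T_f > T_i$; INB requires $DIN(0) > 0$; phase
  thresholds must lie strictly in $(0, 1)$. Each violation fails fast with a
  named argument.
* Validation of incubation tables reports row-level diagnostics (negative
  concentrations, duplicated time-replicate pairs, missing columns).

Test and validation problem sizes: recovery experiments use 200 simulated
noisy series (noise SD 2 µmol L⁻¹) for parameter errors and 200 simulated
incubations of the `sample_A_like` preset for rate errors; consistency
checks use dense grids of 500–8000 points. These sizes give stable medians
while keeping the full suite in the tens of seconds on a single CPU.

## Known limitations

* The Boltzmann form is symmetric about $t_0$; genuinely asymmetric
  accumulation (e.g. abrupt onset with slow saturation) is approximated, and
  the fitted $t_0$ may fall outside the observation window for purely
  concave series — the rate maximum is then reported at the window edge,
  which is the correct reading of such data.
* Average rates from fitted endpoints depend (weakly) on the window ΔT; no
  single convention fits all designs, so the window is explicit everywhere.
* INB labels are threshold classifications on replicate means; they carry no
  uncertainty statement.
* Reported parameter covariances come from the local curvature at the
  optimum and understate uncertainty when residuals are autocorrelated, as
  time-series residuals often are.
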