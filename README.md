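# nitrikin

Nitrification kinetics from incubation time series by Boltzmann curve fitting.

## The problem

Potential nitrification rates of an activated-sludge (or sediment/water)
sample are measured by incubating a slurry in the dark under aeration and
sampling the supernatant every few hours for ammonium, nitrite and nitrate
(µmol L⁻¹). Nitrification is a two-step, non-linear process — ammonia
oxidation (AO, NH₄⁺ → NO₂⁻) followed by nitrite oxidation (NO, NO₂⁻ → NO₃⁻) —
so estimating rates by linear regression through two or three points is
error-prone. `nitrikin` implements the curve-fitting alternative used in
nitrification ecophysiology:

1. **Fit** the cumulative oxidized-nitrogen series with the four-parameter
   Boltzmann sigmoid

   y(t) = A2 + (A1 − A2) / (1 + exp((t − t0)/dt)),

   using the NOₓ⁻ (= NO₂⁻ + NO₃⁻) series for AO and the NO₃⁻ series for NO.
2. **Average rates** over a window \[Tᵢ, T_f\] from fitted endpoints:
   V̄ₐ = ([NOₓ⁻]\_final − [NOₓ⁻]\_initial)/ΔT and
   V̄ₙ = ([NO₃⁻]\_final − [NO₃⁻]\_initial)/ΔT.
3. **Instantaneous rates** from the analytic first derivative
   dy/dt = (A2 − A1)·e^u / (dt·(1 + e^u)²), u = (t − t0)/dt, which peaks at
   (A2 − A1)/(4·dt) exactly at t = t0; lag/exponential/plateau phases are
   segmented where the derivative crosses a fraction of that maximum.
4. **Mass balance** via the index of nitrogen balance,
   INB(t) = DIN(t)/DIN(0) with DIN = [NH₄⁺] + [NO₂⁻] + [NO₃⁻]:
   INB < 1 flags net nitrogen loss (denitrification, anammox, assimilation),
   INB > 1 net release by organic-matter mineralization.

A two-step nitrification ODE simulator (Monod kinetics, logistic induction
ramps, first-order loss, zero-order mineralization) generates
seed-reproducible synthetic incubations with known ground truth, used to
validate parameter and rate recovery end to end.

## Worked example

Simulate a delayed-nitrite-oxidation incubation (68 h, sampled every 6 h,
3 replicates, noise SD 2 µmol L⁻¹) and analyze it:

```r
library(nitrikin)
sim <- simulate_incubation(sim_preset("sample_A_like"))
rep <- analyze_sample(sim$series)
rep
#> Nitrification analysis over [0, 66] h
#>
#>  rate analyte    A1    A2    t0     dt v_avg v_max t_at_vmax lag_end
#>    Va     NOx 1.033 508.0 39.80 10.656 6.898 11.90     39.80   1.044
#>    Vn     NO3 9.404 491.5 48.79  9.758 6.187 12.35     48.79  13.300
#>  plateau_start     r2  n
#>             66 0.9991 12
#>             66 0.9984 12
#>
#> NH4+: 470.7 -> min 17.82 at 66 h -> final 17.82 umol/L
#> Final INB = 0.990 (balanced)
```

Reading the table: the NOₓ⁻ sigmoid rises from ~1 to ~508 µmol L⁻¹ with
inflection at 39.8 h, giving a mean AO rate V̄ₐ of 6.9 µmol L⁻¹ h⁻¹ over the
sampled window and a maximum instantaneous rate of 11.9 µmol L⁻¹ h⁻¹ at the
inflection; nitrite oxidation (from the NO₃⁻ fit) peaks later (48.8 h), which
is why nitrite transiently accumulates in this regime. The final INB of 0.99
says total inorganic nitrogen was conserved to within 1%.

Individual pieces are available as ordinary model objects:

```r
fit <- rep$fits$NOx          # a "boltzmann_fit"
coef(fit); summary(fit); plot(fit)
predict(fit, 44, type = "rate")   # instantaneous Va at 44 h
segment_phases(fit)               # lag end / plateau start (h)
compute_inb(sim$series)           # INB trajectory with labels
```

A command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/nitrikin", package="nitrikin"))')" \
    demo --preset sample_A_like --out-dir run1 --seed 42
```

`run_pipeline()` / the `demo` and `analyze` verbs write a run directory with
the resolved configuration snapshot, input hash or simulator config, all
output tables (`rates.csv`, `fits.csv`, `inb.csv`, `grids.csv`), a JSON
report and a log — rerunning with the same config and seed reproduces the
files byte-for-byte.

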