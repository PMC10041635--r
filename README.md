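# protodebor

Mechanistic prediction of aqueous **protodeboronation** rates of boronic
acids as a function of pH.

Protodeboronation — replacement of a boronic acid's C–B bond by C–H — is
the principal degradation side reaction competing with Suzuki–Miyaura and
related couplings in water. Whether it matters for a given reaction
depends enormously on pH: the observed first-order rate constant
k_obs spans eleven orders of magnitude (log₁₀ k from −9, a ~22-year
half-life, to +2, ~7 ms) across pH 0–14. This package is for chemists and
modellers who want that pH–rate profile *in silico*, from three inputs per
molecule: a structural category, acidity constants (pKa and, for basic
substrates, pKaH), and one DFT-computed characteristic energy difference
ΔE per active pathway.

## The model

Protodeboronation proceeds through up to seven parallel pathways
(k₁, k₂, k₂Ar, k₂cat, k₃, k₄, k₅); the active subset is a function of the
structural class (e.g. plain aryl → k₂Ar only; basic five-membered
heterocycles → k₁, k₂, k₃, k₄). Each pathway's log₁₀ k vs pH curve is
piecewise linear with fixed slopes (k₁: −1; k₂/k₂Ar: +0.75 rising to a
plateau above pKa; k₂cat: ±2 tent at pKa; k₃: +2 toward pH 14; k₄:
±0.75 around the zwitterion plateau [pKaH, pKa]; k₅: −0.75), and its
maximum — the plateau level L — obeys a linear free-energy relationship

  L_n = a_n·ΔE_n + b_n

calibrated per pathway by ordinary least squares against measured curves.
The observable profile is the sum over pathways in linear rate space,

  k_obs(pH) = Σ_n k_n(pH),

capped to log₁₀ k ∈ [−9, +2]. Accuracy is assessed by leave-one-out
cross-validation by molecule. A competing-reaction simulator
(A + B → C coupling vs A → D and A + A → A + D protodeboronation)
translates predicted rates into yield consequences, and a synthetic-data
generator with known ground truth underpins the test suite.

## Worked example

```r
library(protodebor)

# a synthetic benchmark with known ground truth: 50 boronic acids,
# 500 (pH, log k) measurements, noise sd 0.2 log units
synth   <- generate_synthetic(synthetic_spec(noise_sd = 0.2, seed = 42))
dataset <- synth$dataset

# calibrate every pathway from the measured curves
points <- extract_calibration_points(dataset)
cals   <- fit_calibrations(points)
cals$k2Ar
#> linear_calibration k2Ar: log10(k_max) = -320.019 * dE -4.00697
#>   (n = 23, R^2 = 0.9904, dE range [-0.01114, 0.009622] hartree)

# predict one molecule's pH-rate profile from its category, pKa and dE
mol  <- dataset$molecules[dataset$molecules$id == "synth_003", ]
prof <- predict_profile(mol, cals)   # category "aryl", pKa 6.14
data.frame(pH = prof$pH_grid, log_kobs = prof$combined)[c(41, 71, 131), ]
#>     pH log_kobs
#> 41   4    -4.58
#> 71   7    -2.97
#> 131 13    -2.97

half_life(-2.97) / 60   # minutes at pH 7
#> [1] 10.78
```

The fitted k₂Ar line says: each +0.001 hartree in the energy difference
costs about 0.32 log-units of rate. For this aryl molecule the profile
rises at 0.75 log-units/pH until its pKa and then plateaus: at pH 4 the
half-life is about seven hours, at pH ≥ 7 about eleven minutes — a substrate
you would couple fast or at low pH. Cross-validating the whole synthetic
dataset:

```r
loocv(dataset)
#> LOOCV report: 50 molecules, 500 points
#>   MAE = 0.3634  MSE = 0.2914  R^2 = 0.9417
```

## Command line

A thin CLI over the same functions ships in `inst/cli/protodebor.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/protodebor.R", package="protodebor"))')" \
    calibrate --molecules M.csv --rates R.csv --out C.csv
# likewise: predict, loocv, simulate, synth; every subcommand takes
# --config cfg.json|yaml and --rules rules.json
```

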