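---
title: "A mechanistic model for pH-dependent protodeboronation rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic model for pH-dependent protodeboronation rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protodebor)
```

## The model

Protodeboronation — hydrolytic replacement of a boronic acid's C–B bond by
C–H — is the dominant degradation route competing with Suzuki–Miyaura and
related couplings in aqueous media. Its observed first-order rate constant
$k_{obs}$ varies by more than ten orders of magnitude with pH, because the
overall reaction is a sum of parallel mechanistic pathways whose individual
rates depend on the speciation (neutral, boronate, protonated-base,
zwitterion) of the substrate.

`protodebor` implements a mechanistic prediction model with three layers:

1. **Active pathways.** Seven pathways are recognised: $k_1$, $k_2$,
   $k_{2Ar}$, $k_{2cat}$, $k_3$, $k_4$, $k_5$. Which subset is active for a
   given boronic acid is a function of its structural class alone — e.g. a
   plain aryl boronic acid degrades only through $k_{2Ar}$, while a
   five-membered basic heterocycle ("other basic heterocycle") activates
   $k_1$, $k_2$, $k_3$ and $k_4$. The class-to-pathway map is shipped as an
   editable JSON rule table together with SMARTS rules that classify a
   SMILES automatically; a category declared in the molecule table always
   wins over the classifier.
2. **Plateau calibration.** Each pathway's log-rate curve has a maximum
   (its *plateau level* $L_n$, in $\log_{10} k$). Across molecules,
   $L_n$ is linear in a characteristic DFT energy difference
   $\Delta E_n$ (hartree) — a linear free-energy relationship — so one
   ordinary-least-squares line per pathway,
   $L_n = a_n \Delta E_n + b_n$, turns quantum-chemical input into a rate
   prediction. Calibration points are *extracted* from measured curves at
   each pathway's anchor pH, where that pathway dominates and
   $\log k_n \approx \log k_{obs}$.
3. **Curve assembly.** Each pathway's $\log_{10} k$ vs pH curve is
   piecewise linear with fixed slopes (in $\log_{10}(k)$/pH):

   | pathway | shape | slopes |
   |---|---|---|
   | $k_1$ | falls from its maximum at pH 0 | $-1$ |
   | $k_2$, $k_{2Ar}$ | rises to a plateau above p$K_a$ | $+0.75$, then $0$ |
   | $k_{2cat}$ | tent peaking at p$K_a$ | $+2$, $-2$ |
   | $k_3$ | rises toward pH 14 | $+2$ |
   | $k_4$ | plateau on the zwitterion window $[\mathrm{p}K_{aH}, \mathrm{p}K_a]$ | $+0.75$, $0$, $-0.75$ |
   | $k_5$ | falls from pH 0 | $-0.75$ |

   The observed rate is the **sum in linear rate space**,
   $k_{obs}(\mathrm{pH}) = \sum_n k_n(\mathrm{pH})$, computed with a
   log-sum-exp formulation for numerical stability, and finally capped to
   $[-9, +2]$ — the span of the measurable data, from a ~22-year to a
   ~7-ms half-life ($t_{1/2} = \ln 2 / k$).

Model quality is assessed by leave-one-out cross-validation *by molecule*:
all measurements of the held-out boronic acid are removed together, the
calibrations are refitted, and the held-out profile is predicted and
compared at its measured pH values on the capped combined curve (the same
quantity a parity plot shows).

## Assumptions

* Rates are first order in substrate within each pathway
  ($k_{2cat}$, which couples two boronic acid molecules, is folded into an
  effective first-order contribution in the pH profile; its bimolecular
  character is exposed separately in the competition simulator).
* Slopes of the rise/fall segments are universal per pathway; all
  molecule-to-molecule variation is carried by the plateau level and the
  acidity constants.
* p$K_a$ and p$K_{aH}$ are independent inputs (p$K_a$ + p$K_{aH}$ ≠ 14 in
  general); when absent they may be imputed as arithmetic means of the
  training molecules — a deliberately crude fallback appropriate only when
  the query resembles the training set.
* Temperature, solvent composition and ionic strength are absorbed by the
  calibration; no Arrhenius modelling is attempted.

## Tunable parameters

All knobs live in a single `algo_config` object
(`default_algo_config()`), overridable from JSON/YAML without code
changes:

* `slopes` — the table above; units $\log_{10}(k)$/pH.
* `anchors` — where each pathway peaks. The $k_1$–$k_4$ rules are fixed by
  the mechanistic model. The text sources do not pin down the anchors of
  $k_{2Ar}$, $k_{2cat}$ and $k_5$, so the defaults are this package's
  choices: $k_{2Ar}$ at pH 14 (it shares the boronate plateau shape of
  $k_2$), $k_{2cat}$ at its tent peak pH = p$K_a$ (the pathway needs
  neutral and anionic substrate simultaneously, maximally co-present at
  p$K_a$), and $k_5$ at pH 0 (it mirrors the acid-side fall of $k_1$ with
  a gentler slope). All three are config-exposed.
* `cap_low`, `cap_high` — $[-9, +2]$ by default; applied to the combined
  curve only, after summation, so per-pathway curves remain inspectable.
* `anchor_tol` (0.25 pH units) — a measurement within this distance of an
  anchor counts as "at" it; beyond it, linear interpolation in
  (pH, $\log k$) between bracketing measurements is used. Kinetic data are
  tabulated on coarse pH grids, so a small tolerance is needed; 0.25 keeps
  the worst-case plateau-edge bias below 0.19 log units.
* `dominance_margin` (6 log units) — governs when an anchor measurement is
  attributed directly to one pathway. See the next section.
* `r_squared_method` — coefficient of determination (default) or squared
  Pearson correlation; the published parity metrics do not state which
  convention was used, so both are available.

## Numerical and design choices

**Anchor attribution vs curve decomposition.** Two active pathways can
share an anchor region ($k_2$ and $k_3$ both peak toward pH 14; $k_1$ and
$k_5$ toward pH 0), and even a nominally dominant pathway is contaminated
by the others' contribution $\log_{10}(1 + 10^{-\delta})$, about 0.04 log
units at a gap of $\delta = 1$. Rather than accept that bias, the
extractor fits all of a molecule's plateau levels jointly to its whole
measured curve (the plateau levels are the only free parameters of the
summed-curve model) and uses the direct anchor reading only when (a) an
actual measurement sits on the pathway's maximum region — interpolating
across a breakpoint kink is systematically biased low — and (b) every
other pathway is at least `dominance_margin` log units slower there. With
the default margin of 6, direct readings carry $< 10^{-6}$ contamination,
which is what makes the noiseless round-trip tests exact. Because the
decomposition uses only the molecule's own measurements, calibration
points are strictly per-molecule, and cross-validation folds are
independent by construction.

**Plateau decomposition.** The joint fit minimises squared residuals of
the capped combined curve. The objective is screened on a fixed grid
(each $L_n \in \{-9, -7, \dots, +1\}$), the best starts are refined by
Levenberg–Marquardt, and — since the combined rate is *linear* in the
weights $10^{L_n}$ — an additional seed comes from a direct least-squares
solve on the uncapped points. That seed is exact on noiseless data and
rescues pathways buried several log units below the dominant one, where
the log-space gradient is nearly flat. The procedure is deterministic:
same input, same output, bit for bit.

**Summation and capping.** Rates are summed in linear space (the
observable is a sum of rates, not of log-rates) via log-sum-exp, so
plateaus at opposite ends of the scale cannot overflow. Capping is
idempotent and applied last, to the combined curve only.

**Degenerate inputs.** Duplicate molecule ids, unknown categories,
non-numeric cells, pH outside $[0, 14]$ and p$K_{aH} \ge$ p$K_a$ are hard
errors at parse time; a mechanism with fewer than two calibration points,
or all-identical $\Delta E$, is dropped (never silently: a warning names
it, and cross-validation records affected molecules under `skipped`).
Predictions for $\Delta E$ outside the training range are returned but
flagged as extrapolations.

## The synthetic generator

`generate_synthetic()` emulates the structure of the reference kinetic
benchmark — about 50 boronic acids and 500 (pH, $\log k_{obs}$) points
spanning pH 0–14 and rates $[-9, +2]$ — with fully known ground truth:
categories drawn from a configurable mix (default: 40% aryl, 20% each of
the two basic-heterocycle classes, and small shares of the rarer classes,
so that uncommon pathways such as $k_3$ and $k_5$ keep only a handful of
calibration points, as in the real data); $\Delta E$ uniform within
per-pathway ranges of order $10^{-2}$ hartree (the $k_{2cat}$ default
range $[-0.0137, +0.0065]$ matches the magnitude reported for that
pathway); generating slopes of order $-10^{2.5}$ log-units/hartree so the
plateau levels span roughly $[-8, -1]$; p$K_a \in [5, 9]$ and
p$K_{aH} \in [1.5, 4.5]$; homoscedastic Gaussian noise in log space
(default sd 0.3 log units — no error model is published, so the simplest
is the default and it is an explicit field).

What passing synthetic tests shows: the pipeline is self-consistent
(noiseless data are reproduced exactly; injected noise propagates to a
cross-validated MAE of $\sigma\sqrt{2/\pi}$, the half-normal mean). What
it does not show: that real boronic acids obey the linear
energy–rate relationships, that the shipped structural taxonomy matches
the full benchmark taxonomy, or that real measurement error is Gaussian
and homoscedastic. The half-normal noise check is run on a single-pathway
(aryl-only) mix at 40 molecules × 15 pH points, because the limit assumes
the held-out prediction error is negligible next to the noise;
multi-pathway mixes add decomposition variance on top.

Test-suite problem sizes are deliberately modest — 6–15 molecules for
pipeline unit tests, the full 50-molecule default for the end-to-end
round trip, $10^5$ fixed steps for the Runge–Kutta reference integration —
chosen as the smallest sizes at which each property is sharply testable.

## The competition simulator

To translate a predicted $k_{obs}$ into consequences for a coupling, the
package integrates the parallel scheme
$A + B \rightarrow C$ (intended coupling, $k_{couple}$),
$A \rightarrow D$ (protodeboronation, $k_{proto}$ — typically a predicted
$k_{obs}$ at the reaction pH) and
$A + A \rightarrow A + D$ (self-catalytic protodeboronation,
$k_{selfcat}$; net consumption of one A, read literally from the scheme),
with a stiff-capable adaptive integrator (relative tolerance $10^{-8}$).
Yield is $C(t_{end})/\min(a_0, b_0)$. pH drift over a reaction — which
can exceed 3 pH units and changes $k_{proto}$ along the way — is *not*
modelled; a user wanting it must supply their own $k_{proto}(t)$
schedule.

## Known limitations

* The structural taxonomy beyond the aryl and basic-heterocycle classes
  is an editable, mechanistically motivated encoding, not an exhaustive
  one; molecules that match no rule must be categorised manually.
* Boronate esters (Bpin and relatives) are out of scope — their pathways
  differ — as is any prediction of the *intended* reaction's rate.
* Mean-value imputation of p$K_a$/p$K_{aH}$ ignores solvent effects
  (the reference measurements are in 50/50 water/dioxane) and should be
  treated as a last resort.
* Rare pathways calibrated on two points ($k_3$, $k_5$ in the reference
  data) fit a perfect line by construction; their $R^2 = 1$ carries no
  evidential weight, and the `deltaE_range` extrapolation flag is the
  more useful diagnostic there.
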