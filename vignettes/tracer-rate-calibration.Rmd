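---
title: "Calibrating 15N tracer rates: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating 15N tracer rates: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n15rates)
library(dplyr)
```

## The measurement and its model

A ¹⁵N tracer incubation spikes a seawater sample with labelled substrate
(¹⁵NH₄⁺ for nitrification and ammonium uptake, ¹⁵NO₃⁻ for nitrate uptake),
incubates it under simulated in-situ light, and measures the concentration
and ¹⁵N atom fraction of the *product* pool (NOₓ, or particulate organic
nitrogen on filters) at the start and end. With product concentrations
$C_0, C_t$, product atom fractions $n_0, n_t$, substrate labelling after
the spike $f^{15}$, and duration $t$, the package computes

$$R_\mathrm{bulk} = \frac{C_0\,(n_t - n_0)}{t\,f^{15}}, \qquad
  R_{15} = \frac{C_t n_t - C_0 n_0}{t}, \qquad
  R_{14} = R_{15}\,\frac{1 - n_\mathrm{sub}}{n_\mathrm{sub}},$$

$$R_\mathrm{in\,situ} = (R_{15} + R_{14})\,\frac{C_i}{C_i + C_{t,\mathrm{tracer}}},$$

where $C_i$ is the ambient substrate concentration and
$C_{t,\mathrm{tracer}}$ the tracer addition. The kinetic alternative fits

$$R = \frac{V_\max\,S}{K_s + S}, \qquad \alpha = \frac{V_\max}{K_s}$$

to a four-level enrichment experiment and evaluates the curve at ambient
substrate.

The in-situ calibration rests on three assumptions, which the package
treats as part of the measurement model rather than options to estimate:

1. **Constant labelling.** $f^{15}$ does not change during the incubation:
   regeneration-driven isotope dilution is negligible over the short (3–12 h)
   incubations, and isotopic fractionation is swamped by the tracer-level
   enrichment. No dilution correction is applied anywhere.
2. **Near-first-order kinetics.** The linear interpolation from the spiked
   rate back to ambient substrate is exact only while the Michaelis–Menten
   response is approximately linear, i.e. while
   $C_i + C_{t,\mathrm{tracer}} < K_s$. `rate_in_situ()` and
   `compare_estimators()` raise a classed warning when a supplied kinetic
   fit says this regime is violated.
3. **Constant rate within the bottle.** Product accumulates linearly over
   the incubation (zeroth-order in time); substrate depletion within the
   bottle is ignored. This is consistent with assumption 1 and with the
   short durations.

### Exact mass balance, not δ-linear mixing

Every mixing, unmixing (carrier subtraction) and blank-correction step is
computed in (amount, atom fraction) space: amounts and ¹⁵N contents add;
atom fractions are amount-weighted means. Mixing δ values linearly is a
low-enrichment approximation that fails badly against a 98 atom-% tracer,
so δ¹⁵N and atom-% exist only at the I/O boundary (columns tagged
`_delta_permil` or `_atom_pct`). The unit conversions are

$$n = \frac{R}{1+R},\qquad R = R_\mathrm{std}\left(1 + \frac{\delta}{1000}\right),$$

with $R_\mathrm{std} = 0.0036765$ (atmospheric N₂) as the default: this
value reproduces the conventional natural abundance of 0.3663 atom-% at
δ¹⁵N = 0 ‰ exactly.

### Which "bulk rate" when the product pool grows

The classical bulk formula uses the *initial* product concentration $C_0$
and assumes the pool is constant. When the pool grows appreciably during
the incubation (routine for PON during uptake experiments), that formula is
biased low by the factor $\frac{f^{15}-n_0}{f^{15}}\cdot\frac{C_0}{C_0+Rt}$.
Because both endpoint concentrations are measured, the package uses the
exact mass-balance form $R_{15}+R_{14}$ — identical to the classical
formula when the pool is constant, exact when it grows — as the
bulk-substrate rate inside `compare_estimators()` and the simulators'
recovery chain. `rate_bulk()` still reports the classical $C_0$-based value
for comparability, and the two are verified to agree algebraically in the
constant-pool case.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `r15_standard` | 0.0036765 | – | ¹⁵N/¹⁴N of atmospheric N₂ |
| `tracer_atom_frac` | 0.98 | – | labelling of the commercial tracer |
| `delta_sd` | 0.2 | ‰ | analytical SD of δ¹⁵N |
| `k_sigma` | 3 | – | SDs defining a reliable enrichment (3 × 0.2 = 0.6 ‰) |
| `light_hours`, `dark_hours` | 12, 12 | h | daily integration of oxidation |
| `uptake_hours` | 16 | h | daily multiplier for light-driven uptake |
| `mld_delta_t` | 0.8 | °C | mixed-layer temperature offset |
| `nitracline_contiguity` | 0.9 | – | gradient fraction defining the steepest range |
| `nitracline_flatness_floor` | 0.05 | µmol L⁻¹ m⁻¹ | minimum gradient for a nitracline |
| `euphotic_fraction` | 0.001 | – | surface-PAR fraction (0.1 % light level) |

Notes on the less obvious choices:

- **Detection limits are per sample**, not a global constant, because the
  product pool spans orders of magnitude over depth (tens of nmol L⁻¹ of
  PON near the surface to ~30 µmol L⁻¹ of NOₓ at depth). The minimum
  detectable atom-fraction increase is computed by *exact* δ→atom-fraction
  conversion at the pool's initial δ, not a linearized sensitivity — the
  difference is negligible at natural abundance but the exact form is
  self-consistent.
- **Daily integration**: oxidation assumes equal 12 h day and night periods
  and requires a light/dark pair; uptake is light-driven and multiplies the
  light-incubation hourly rate by 16. Whether the ×16 convention should
  ever include a dark component is ambiguous in practice; the package
  applies it to the light rate only, and the multipliers are configurable.
- **Negative rates are retained** and flagged `below_dl`, never clamped to
  zero: truncation would bias averages of replicate and profile data.
- **Nitracline rule**: the gradient is computed on raw adjacent sample
  pairs with no smoothing; the "steepest range" is the longest contiguous
  run of pairs whose gradients reach ≥ 90 % of the maximum (ties resolved
  toward the run holding the maximum, then the shallower run), and the
  nitracline depth is the mean of the range endpoints. There is no
  community-standard numeric delimitation of "the range with the steepest
  gradient"; the 90 % rule is this package's declared, configurable choice.
  The flatness floor of 0.05 µmol L⁻¹ m⁻¹ declares "no nitracline" for
  profiles (e.g. eutrophic coastal stations) whose maximum gradient is
  indistinguishable from nutrient-analyzer noise propagated onto 5–10 m
  bottle spacings, while remaining an order of magnitude below real
  nitracline gradients (~1 µmol L⁻¹ m⁻¹).
- **Transition depth**: the uptake→nitrification crossover must persist
  for ≥ 2 consecutive samples below the crossing; single-sample sign flips
  in co-occurring, comparable profiles return "co_occurring" rather than a
  depth. Nitrification dominant from the shallowest sample returns
  "surface_dominated". Both are distinct, non-error outcomes.
- **Mixed-layer depth interpolates** linearly between the bracketing
  bottles rather than snapping to a sample depth; with 5–20 m bottle
  spacing, snapping would quantize the answer by half the spacing.

## Kinetic fitting

`fit_mm()` fits the saturation curve by nonlinear least squares with
$V_\max$ and $K_s$ log-parameterized: positivity is enforced by
construction and the parameterization is robust for sparse four-level
designs. Start values are $V_{\max,0} = \max(R)$ and
$K_{s,0} = \mathrm{median}(S)$; standard errors are mapped back from the
log scale by the delta method. The `scaleOffset` convergence option is set
so that noise-free (zero-residual) designs converge cleanly. If the
Gauss–Newton iteration fails outright, a Nelder–Mead direct search on the
same objective takes over (standard errors are then reported as `NA`), and
the `converged` flag always reports the optimizer's own verdict. Replicates
are fitted jointly, not averaged first: with duplicate bottles at four
levels this uses all 8 points and keeps the residual degrees of freedom
honest. Unweighted least squares is the default; `weights = "relative"`
(1/rate², constant-CV) is available for series spanning large rate ranges.
The abscissa is the *total* substrate seen by the organisms, ambient plus
added tracer.

The tests verify the fit against an independent brute-force grid search
over a $(V_\max, K_s)$ lattice, and a 200-series simulation at 5 %
multiplicative rate noise puts the median |bias| of both parameters well
under 10 % (typically < 1 %).

## What the synthetic generators emulate — and what they do not

`simulate_incubation()` reproduces the experimental design: spikes of
20 nmol L⁻¹ (oxidation, 12 h) or 10 nmol L⁻¹ (uptake, 3 h) into ambient
pools of 1–74 nmol L⁻¹, duplicate bottles under paired light/dark
conditions, kinetic series at additions of {10, 100, 500, 2000} nmol L⁻¹,
concentration noise of CV 3.5 % and δ¹⁵N noise of SD 0.2 ‰ (the documented
analytical precisions). The true rate is the Michaelis–Menten rate at total
substrate, times a light factor (nitrification is inhibited in the light,
default factor 0.5; uptake is light-driven, dark factor 0.3). Product ¹⁵N
accumulates by exact mass balance at constant rate. In
`simulate_kinetic_experiment()` the per-level incubations are generated
noise-free and the 5 % multiplicative noise is applied to the assembled
rates, matching how a rate-level error budget is usually stated.

`simulate_station()` builds a stratified oligotrophic water column:
isothermal mixed layer over a linear thermocline (the kink placed so the
0.8 °C criterion is met exactly at the nominal MLD of 40 m), exponential
PAR with k = 0.06 m⁻¹, a logistic nitracline centred at 70 m, Gaussian
nitrite (85 m) and chlorophyll (75 m) maxima, and unimodal uptake
(peak 30 m) and nitrification (peak 110 m) profiles whose amplitudes are
anchored so the crossover falls exactly at the nitracline. The station
noise levels are instrument-grade: 0.01 °C temperature, 5 % PAR and
fluorescence, 1 % deep nitrate (auto-analyzer precision), 10 % rates.

The generators deliberately do **not** model: substrate depletion or
regeneration within bottles (no ODE pool dynamics), diel light forcing
beyond the fixed 12/12 and ×16 conventions, multi-substrate competitive
kinetics, temperature/pH dependence of $K_s$, density-based mixed-layer
criteria, or pigment-based community composition. Passing recovery tests
therefore demonstrates that the *calculation chain* is correct and that the
feature detectors are robust to analytical noise — not that the calibration
removes ecological complications (grazing, regeneration, bottle effects)
that real incubations face.

Problem sizes in the recovery studies — 200 kinetic series, 100 stations,
profiles of 41 depths — were chosen as the smallest giving stable
percentile estimates; they run in seconds.

## Degenerate inputs and numerical conventions

- δ ≤ −1000 ‰, atom fractions outside (0, 1), all-zero mixtures, blanks
  exceeding the sample, carrier heavier than the mixture: classed errors
  (`n15rates_*`), never silent NA.
- Isothermal profiles (no MLD), flat nitrate (no nitracline), flat series
  (no extremum), no persistent crossover: `NA` results with a status where
  relevant — these are findings, not errors.
- Ties in extremum detection break toward the shallower depth; extrema on
  the first/last sample are flagged as boundary extrema.
- Internal units are fixed (nmol N L⁻¹, hours, metres positive downward,
  atom fraction); conversions happen only in the readers/writers.
- All randomness is seedable; generator functions restore the caller's RNG
  stream.

## A worked chain

```{r chain}
truth <- incubation_truth(vmax = 22, ks = 1000, ambient_substrate = 20)
rec <- simulate_incubation(truth, spike = 20, replicates = 1,
                           light = "dark", noise = FALSE)
fit <- fit_mm(simulate_kinetic_experiment(truth, noise = FALSE))
compare_estimators(rec, fit)
```

With ambient and tracer both 20 nmol L⁻¹ and $K_s$ = 1000 nmol L⁻¹, the
bulk rate overestimates the ambient-substrate rate by the closed-form
factor $\frac{(C_i+C_t)(K_s+C_i)}{C_i(K_s+C_i+C_t)} \approx 1.96$, and the
in-situ calibration recovers the true rate to within
$\frac{C_t}{K_s+C_i+C_t} \approx 2\,\%$.

## Known limitations

- The in-situ calibration degrades as total substrate approaches $K_s$;
  the package warns but cannot correct beyond the first-order regime —
  that is what the kinetic approach is for.
- Standard errors from 4-level duplicate designs are asymptotic
  (linearized) and optimistic when the top level barely saturates; the
  tests document that poorly spanned designs inflate `ks_se`.
- `read_*` functions validate rows independently; cross-row consistency
  (e.g. one initial bottle shared by several incubations) is the caller's
  responsibility.
- Feature detectors assume a single station per call; multi-station tables
  must be split first (the CLI does this by the `station` column).
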