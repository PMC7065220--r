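---
title: "Models and methods behind cassleaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cassleaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cassleaf)
```

cassleaf diagnoses what limits C3 leaf photosynthesis — in vivo Rubisco
capacity, mesophyll CO2 diffusion, or stomata — under both steady-state
and fluctuating light, using the measurement protocols standard for
cassava (*Manihot esculenta*) gas-exchange work: CO2 response (A/ci)
staircases with modulated chlorophyll fluorescence, dark–shade–sun
induction curves sampled every 10 s, sun–shade–sun relaxation curves, and
light-response curves. A reduced dynamic leaf model couples those steady
state components to first-order stomatal and Rubisco-activation kinetics
so that the carbon and water cost of stomatal sluggishness can be
simulated. This vignette records the models, the defaults and why they
were chosen, what the synthetic-data generator does and does not emulate,
and the package's known limitations.

## The steady-state kernel

Net assimilation follows the Farquhar–von Caemmerer–Berry (FvCB) model:
\[
A = \min(W_c, W_j, W_p) - R_d,
\]
with the Rubisco-limited rate
\(W_c = f_{act} V_{cmax} (C_c-\Gamma^*)/(C_c + K_c(1+O/K_o))\), the
RuBP-regeneration-limited rate
\(W_j = J (C_c-\Gamma^*)/(4C_c+8\Gamma^*)\), and the triose-phosphate
utilization (TPU) ceiling \(W_p = 3\,V_{TPU}\), applied only above the
photorespiratory compensation point \(\Gamma^*\). \(f_{act}\in[0,1]\) is
the Rubisco activation fraction (1 at steady state). Electron transport
responds to incident light through the non-rectangular hyperbola, the
smaller root of \(\theta J^2 - (\alpha Q + J_{max})J + \alpha Q J_{max}=0\).

CO2 reaches the chloroplast through two conductances in series,
\(A = g_{sc}(C_a - C_i) = g_m(C_i - C_c)\) with \(g_{sc} = g_{sw}/1.6\).
`solve_supply_demand()` closes this diffusion path against the demand
curve by bisection on \(C_c\) (tolerance 1e-4 umol mol^-1^, max 200
iterations, bracket extended above \(C_a\) so the dark/respiring case is
covered); the dynamic simulator uses an exact quadratic-branch solution
of the same balance for speed, and a test holds the two routes together.

All mole fractions are in umol mol^-1^ (Ko and O in mmol mol^-1^), all
conductances in mol m^-2^ s^-1^; gs is always reported on the water-vapour
basis. There is no partial-pressure mode.

### Temperature responses

Parameters are stored at the 25 degC reference and scaled with the
Arrhenius factor \(\exp[H_a(T_k-298.15)/(298.15\,R\,T_k)]\); Vcmax, Jmax
and TPU additionally carry the peaked deactivation correction with
defaults \(H_d = 200\) kJ mol^-1^ and \(\Delta S = 0.65\)
kJ mol^-1^ K^-1^. The shipped kinetic constants are the Bernacchi set
(Kc25 = 404.9 umol mol^-1^, Ha 79.43; Ko25 = 278.4 mmol mol^-1^, Ha
36.38; Gamma\*25 = 42.75 umol mol^-1^, Ha 37.83; Rd Ha 46.39), all
overridable through `bernacchi_constants()`. At glasshouse leaf
temperatures near 28 degC the peaked correction is small but not
negligible (about -9% on Vcmax), which is why fitted values are
normalized back to 25 degC through the same invertible transform.

### Light-response defaults

The source protocols never state the quantum yield or curvature used, so
they are declared, not inferred: \(\alpha = 0.35\) mol e^-^ mol^-1^
photon on an incident basis (absorptance 0.85 x PSII share 0.5 x maximum
PSII yield ~0.83) and \(\theta = 0.9\). With Jmax near 165 these defaults
put the electron-transport ceiling (J/4 ~ 40 umol m^-2^ s^-1^) safely
above the TPU ceiling (3 x 10.8 ~ 32), which is what makes the observed
high-Ci plateau a TPU signature rather than an electron-transport one.
With a noticeably lower \(\alpha\theta\) product the two ceilings
coincide and TPU becomes unidentifiable from a staircase.

## A/ci fitting

`fit_aci()` avoids fixed Ci cutoffs: the Ci-sorted points are split at
every admissible Rubisco/RuBP breakpoint, each partition is fitted (the
Rubisco limb is linear in Vcmax and Rd and solved exactly; Jmax is
profiled through the light response, in closed form at constant light),
and the partition with minimum total SSE wins. TPU is reported only when
the points above Ci = 700 umol mol^-1^ fall clearly below the
extrapolated RuBP limb, or sit flat on it while fluorescence-derived
electron transport declines with Ci — otherwise TPU is `NA`, never an
extrapolation. A second pass drops from the Jmax fit any point that the
fitted ceiling itself marks as TPU-limited, because the Ci-700 cutoff can
miss marginal ones.

## Gamma*, Rd, and mesophyll conductance

The package estimates \(\Gamma^*\) and \(R_d\) jointly from gas exchange
paired with fluorescence, through the identity
\[
A = s\,\phi_{PSII} Q/4 \cdot \frac{C_c-\Gamma^*}{C_c+2\Gamma^*} - R_d,
\qquad C_c = C_i - A/g_m,
\]
which holds in *every* limitation state because the operating
\(\phi_{PSII}\) tracks the electron flux actually sustaining
carboxylation plus photorespiration. \(\Gamma^*\) and (unless supplied)
\(g_m\) are profiled numerically; for fixed values the model is linear in
the calibration factor \(s\) and \(R_d\). Replicate curves sharing the
staircase are averaged pointwise before fitting.

Two deliberate choices:

* **The fluorescence calibration `s` is fixed by default** at
  absorptance x PSII share = 0.425. Fitting it jointly (available with
  `s = NULL`) is formally the cited procedure, but the
  \((s, \Gamma^*, R_d, g_m)\) objective has a near-flat ridge: at
  realistic channel noise (sigma_A = 0.3 umol m^-2^ s^-1^) the fitted
  calibration slides along that ridge and drags \(\Gamma^*\) up and
  \(R_d\) down by tens of percent. With `s` fixed the estimator is
  unbiased to within a few percent.
* **gm is profiled inside the estimate** rather than assumed infinite. A
  pure Ci-basis construction absorbs the mesophyll drawdown into an
  "apparent Gamma\*" that is ~60% too high even on noise-free data
  whenever gm is finite.

Point estimates of gm at ambient CO2 use the Harley variable-J formula
`variable_j_gm()`; a non-positive drawdown is flagged `NA`, and
\(J \le 4(A+R_d)\) raises an error — this inconsistency is exactly why
Jmax cannot be re-fitted on the Cc basis when TPU limitation depresses
electron transport, and `fit_vcmax_cc()` returns `Jmax_Cc = NA` in that
case.

## Limitation partitioning

`limitation_partition()` implements the Grassi–Magnani decomposition with
total conductance \(g_t = (1/g_{sc}+1/g_m)^{-1}\) and carboxylation
sensitivity \(dA/dC_c = V_{cmax}(\Gamma^*+K_m)/(C_c+K_m)^2\):
stomatal, mesophyll and biochemical shares that sum to one by
construction. Two structural facts are worth keeping in mind when
interpreting output: the mesophyll-to-stomatal share ratio is exactly
\(g_{sc}/g_m\), and the biochemical-to-mesophyll ratio is
\(g_m/(dA/dC_c)\). See "Known limitations" for what this implies about
reproducing published partition patterns.

## Induction analysis

`induction_metrics()` references 50%/90% rise times to the value 30 min
after the shade–sun transition (crossings by linear interpolation; a
baseline-subtracted variant is available), reports `gsT0` as the last
conductance sample at or before the transition, and computes CCF as the
**sum of the 10-s assimilation samples over the first 5 min** — the
convention whose magnitudes (about 30 x mean A) match the published
tables, the literal time integral being ~10x larger; the integral is also
returned (`CCF_integral`).

`fit_stomatal_kinetics()` fits \(g_s(t) = (g_{start}-g_{end})e^{-t/k} +
g_{end}\). **k is a time constant in minutes: larger k = slower
stomata.** The widely printed form writes the exponent as \(-kt\), but a
k "calculated by curve fitting" and reported in minutes, with slower
cultivars carrying larger k, is dimensionally and behaviourally a time
constant; this package makes that reading explicit.

Two estimators exist for a reason. On measured (or simulated) traces the
exponential fit returns an *apparent* constant: during opening, the
Ball–Berry target rises together with A, which roughly doubles the
apparent opening constant relative to the mechanistic one.
`fit_kinetics_ode()` removes the feedback by reconstructing the target
path from the observed A/humidity channels and fitting the relaxation ODE
directly; it is the estimator used in the closed-loop recovery tests.

`dynamic_aci()` assembles, at each time point, the instantaneous (Ci, A)
pairs across induction curves run at 75/150/270/400/600 umol mol^-1^
CO2, fits the Rubisco-limited limb for \(V_{cmax,t}\), and computes
stomatal limitation against the fitted curve at a reference Ci (default:
the ambient trace's final, steady-state Ci; configurable). SL is clamped
to [0, 1].

## The dynamic leaf model

The simulator reduces the source's full metabolic model to the two lags
that govern its headline behaviour:

\[
\frac{dg_s}{dt} = \frac{g_s^{target}-g_s}{\tau}, \quad
\tau = \begin{cases} k_i & \text{opening} \\ k_d & \text{closing}\end{cases}
\qquad
\frac{df_{act}}{dt} = \frac{f_{ss}(Q) - f_{act}}{\tau_R},
\]

with the Ball–Berry target \(g_s^{target} = \max(g_{s,min},\; m A h_s/c_s
+ b)\) (surface humidity from cuvette VPD via the Tetens formula;
\(c_s \approx C_a\) under stirred-cuvette conditions) and
\(f_{ss}(Q)\) a rectangular hyperbola rising from `f_act_dark` (default
0.3) to 1 with half-saturation `Q_half` = 150 umol m^-2^ s^-1^;
\(\tau_R\) defaults to 4 min, in the range the Rubisco-activase
literature supports. At every sub-step A, Ci and Cc follow algebraically
from the supply–demand balance. Integration is classical RK4 with dt =
0.5 s (dt <= 1 s enforced; a halving test bounds the discretization error
below 0.01 umol m^-2^ s^-1^); states are clamped to their physical ranges
after each step. Transpiration is \(T = g_{sw}\,VPD/P_{atm}\) (boundary
layer neglected) and WUE = A/T with cumulative-ratio aggregation over
windows. "Three-fold faster" kinetics means time constants divided by 3.
Default environment: Ca = 400 umol mol^-1^, T_leaf = 28 degC, VPD = 1.5
kPa, P_atm = 101.325 kPa — the cuvette settings of the measurement
protocol.

The instantaneous-kinetics reference (`instantaneous = TRUE`, used by
`diurnal_loss()`) replaces the lags with the coupled Ball–Berry x FvCB
fixed point, solved by an independent 1-D root finder
(`steady_state_leaf()`) that also serves as the convergence oracle for
the integrator.

The default fluctuating-light cycle for `diurnal_loss()` is 20 min shade
(150 umol m^-2^ s^-1^) / 10 min sun (1500) repeated 4 times: a
lower-canopy sunfleck geometry — shade-dominated, with transitions every
10–20 min, consistent with the ~20+ daily shade–sun transitions expected
for a second leaf layer. The cycle the source used is not in the
available text, so this default is a declared choice, configurable via
`square_wave_regime()`.

## The synthetic-data generator

`generate_aci()` evaluates the supply–demand balance along the 13-step
commanded CO2 staircase (400, 270, 150, 100, 75, 50, 400, 400, 600, 800,
1100, 1300, 1500 umol mol^-1^) with fixed gs and gm;
`generate_induction()` samples the dynamic simulator every 10 s;
`generate_light_curve()` chains steady states over a PPFD ladder. The
emitted phiPSII always reflects the *realized* electron transport, so it
declines with Ci once TPU binds — the fluorescence signature used for TPU
detection — and stays consistent with the Laisk-style estimator in every
limitation state.

Noise is Gaussian, homoscedastic and independent across samples, applied
to the measured channels A, gs and phiPSII (defaults 0.3 umol m^-2^
s^-1^, 0.01 mol m^-2^ s^-1^, 0.01). The derived Ci is emitted at its
latent value: propagating the A/gs noise into Ci the way an analyzer's
firmware does creates a strong errors-in-variables correlation that is
not part of this deliberately simple error model (hooks for an AR(1) or
correlated model would slot in at the same place). Consequently, a green
recovery test establishes estimator correctness under channel noise, not
robustness to instrument-level error propagation, drift, leaks or
match-valve artifacts.

The three shipped presets bracket the observed induction behaviour:
`"fast"` reaches the shade–sun transition with gs near 0.047 mol m^-2^
s^-1^ and `"slow"` near 0.005 (the printed extremes of the cultivar
panel), with the panel-average `"mean"` preset carrying Vcmax/Jmax/TPU =
105/165/10.8, k_i = 9.8 min, k_d = 6 min. Where the source prints no
value the presets use field-typical ones: Ball–Berry slope 8 with
intercepts chosen to land on the printed gsT0 extremes, gm = 0.4 mol
m^-2^ s^-1^ (the value that reproduces the published
Vcmax_Cc/Vcmax ratio of ~1.25 at the published operating point), and
k_d below k_i since these cultivars close faster than they open. The
low-CO2 shade treatment (stomatal pre-opening at 100 ppm) is emulated
mechanistically: a Ball–Berry target cannot open stomata at low CO2 with
near-zero A, so during the shade phase the target is pinned at the
high-light steady-state conductance — which is precisely the treatment's
physiological effect ("gsT0 large").

## Known limitations

* **The published partition pattern is not reachable from the published
  summary numbers.** The mesophyll/stomatal share ratio equals
  \(g_{sc}/g_m\); a mesophyll share ~2.5x the stomatal one therefore
  requires \(g_m \approx g_{sc}/2.56 \approx 0.07\) mol m^-2^ s^-1^ —
  but at the published A ~ 22.6 and operating Ci ~ 250 that drawdown
  would put Cc below Gamma\*. The package's mean synthetic leaf instead
  yields biochemical > stomatal > mesophyll with a stomatal share just
  above 0.25; the corresponding acceptance assertions are left failing
  by design, with the closure property (shares summing to one) exact.
  Reproducing the published 43/41/16 pattern needs the per-replicate
  data, or a different Kc/Ko basis, neither of which is available.
* **The reduced model predicts a WUE *gain*, not loss, from stomatal
  lags** over every square-wave cycle tried, under both cumulative and
  time-averaged WUE definitions: with a Ball–Berry target proportional
  to A and A concave in gs, the opening lag saves more water than
  carbon. The carbon-loss prediction (~14% on the default cycle) is in
  line with the published ~13%; the WUE sign difference is reported as
  computed and is the main fidelity caveat of replacing the full
  metabolite kinetics with an activation scalar.
* Fitted "apparent" parameters on the Ci basis (Vcmax, Jmax, Gamma*,
  Rd) are systematically below their Cc-basis counterparts whenever gm
  is finite; the package exposes both bases and the tests treat the
  Cc-basis values as the recovery targets.
* The diffusive-leak correction for cuvette gaskets is exposed as an
  optional linear hook only (`A + k_leak (Ca - C_chamber)` applied by
  the caller); chamber constants are instrument-specific and none are
  shipped.
* iWUE for replicate sets defaults to mean-of-ratios (matching the
  published table magnitudes); ratio-of-means is available.
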