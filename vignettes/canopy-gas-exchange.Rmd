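---
title: "Whole-canopy gas exchange: models, fits and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-canopy gas exchange: models, fits and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyflux)
```

## What the package computes

`canopyflux` analyses whole-canopy gas exchange measured with flow-through
canopy chambers, of the kind used to quantify crop water- and nitrogen-use
efficiency in container and small-plot experiments. The workflow has five
stages, each usable on its own:

1. **Chamber fluxes.** A chamber of ground area $a$ receives a molar air
   flux $u_e$; the logger records entrance conditions and exit-minus-
   entrance differentials every 12 minutes. Canopy transpiration and net
   photosynthesis follow from the flow-through mass balance:
   $$E_c = \frac{1000\,u_e\,VP_{dif}}{a\,[P - (VP_{in} + VP_{dif})]},
   \qquad
   A_{c,net} = -\Big(\frac{u_e\,CO_{2,dif}}{a} + 10^{-3} E_c\,CO_{2,out}\Big),$$
   with $E_c$ in mmol H$_2$O m$^{-2}$ s$^{-1}$ and $A_{c,net}$ in
   µmol CO$_2$ m$^{-2}$ s$^{-1}$; the second term corrects exit CO$_2$ for
   dilution by transpired water. Gross photosynthesis is
   $A_{c,gross} = A_{c,net} + R_c$, where canopy respiration at night is
   read directly from the CO$_2$ balance and during the day follows the
   fitted exponential temperature response
   $$R_c = R_{c,25}\exp\!\Big[\frac{E_{Rc}\,(T_{air}-25)}
   {298\,R\,(T_{air}+273)}\Big].$$

2. **Canopy structure.** Light attenuates with cumulative leaf area
   following Beer's law, $I_i/I_0 = e^{-k_L\,LAI_i}$, and specific leaf
   nitrogen declines as $SLN_i = SLN_0\,e^{-k_n\,LAI_i}$, so cumulative
   nitrogen above depth $i$ is $N_i = SLN_0(1-e^{-k_n LAI_i})/k_n$. Both
   extinction coefficients are fitted by Levenberg–Marquardt least squares
   on untransformed values. The nitrogen coefficient itself declines
   roughly exponentially with canopy size, which `fit_kn_lai()` captures
   with $k_n = c\,e^{-d\,LAI}$.

3. **Sun/shade canopy model.** Leaves are split into a sunlit and a shaded
   big-leaf fraction. The sunlit leaf area is $(1-e^{-k_b\,LAI})/k_b$ with
   $k_b$ the direct-beam extinction coefficient from leaf inclination
   (default 15°) and solar elevation; absorbed PAR per fraction accounts
   for leaf scattering and canopy reflection, and canopy nitrogen is
   allocated by integrating the SLN profile weighted by the sunlit
   probability, so allocation is exactly conservative. Each fraction runs
   a C3 (FvCB) leaf model — Rubisco- and electron-transport-limited rates
   with Arrhenius temperature scaling, $V_{cmax25}$ proportional to
   nitrogen above a base SLN — coupled to a stomatal conductance
   proportional to assimilation, and transpires according to
   Penman–Monteith with explicit boundary-layer ($r_{bh}$, $r_{bw}$) and
   stomatal ($r_{sw}$) resistances.

4. **Water limitation.** When the water available for transpiration $E_a$
   falls short of the potential $E_p$, the stomatal resistance that
   delivers exactly $E_a$ follows from inverting Penman–Monteith:
   $$r_{sw,a} = \frac{(E_p - E_a)(s\,r_{bh} + \gamma\,r_{bw})}{\gamma E_a}
   + r_{sw,p}\frac{E_p}{E_a},$$
   and photosynthesis is recomputed with stomata so constrained. The
   allowance is partitioned between the fractions in proportion to their
   potential transpiration. Non-stomatal (biochemical) stress effects are
   deliberately out of scope.

5. **Normalization and efficiencies.** The chamber wall warms the air,
   raises vapour pressure and draws down CO$_2$ relative to open air.
   Running the canopy model under both micro-environments yields
   per-record correction factors $f_{Ec} = E_{cp,air}/E_{cp,chamber}$ and
   $f_{Ac} = A_{c,gross,air}/A_{c,gross,chamber}$ (the latter with the
   water-limited model driven by corrected and measured transpiration
   respectively). Daily efficiencies are
   $PWUE_c = 1000\,A_{c,gross}/E_c$ (mmol CO$_2$ per mol H$_2$O) and
   $PNUE_c = A_{c,gross}/N_c$ (mol CO$_2$ d$^{-1}$ per g N).

## Tunable parameters and defaults

`leaf_params()` holds the leaf-level configuration. The defaults describe
a nitrogen-rich, thin-leaved C3 annual and were chosen once so that daily
simulations over the measured treatment canopies land inside the
physiological envelopes reported for such crops (daily $PWUE_c$ between
4 and 7.5 mmol mol$^{-1}$; instantaneous maxima of order 10 mmol H$_2$O
and 40 µmol CO$_2$ m$^{-2}$ s$^{-1}$):

| parameter | default | units | meaning |
|---|---|---|---|
| `chi_vcmax` | 120 | µmol CO$_2$ (g N)$^{-1}$ s$^{-1}$ | slope of $V_{cmax25}$ vs SLN |
| `sln_base` | 0.2 | g N m$^{-2}$ | non-photosynthetic leaf N |
| `rjv` | 1.9 | – | $J_{max25}/V_{cmax25}$ |
| `alpha_e`, `theta_j` | 0.425, 0.7 | – | light-response quantum yield and curvature |
| `a1` | 2.0 | – | stomatal slope on assimilation |
| `d0` | 10 | kPa | stomatal VPD sensitivity (large = weak response) |
| `g0` | 0.01 | mol m$^{-2}$ s$^{-1}$ | residual conductance (keeps night-time Penman–Monteith defined) |
| `leaf_width` | 0.08 | m | boundary-layer length scale |
| `leaf_angle` | 15 | ° | inclination for the beam extinction |

Two of these deserve comment. The stomatal humidity response is kept weak
(`d0 = 10`) because the conductance formulation this package emulates
couples stomata to assimilation, not to vapour pressure deficit; a strong
Leuning-type VPD term would cancel the well-documented effect of chamber
warming on potential transpiration, which the normalization stage exists
to correct. Second, net radiation is proxied as `rn_par_mult` (default
1.1) times absorbed PAR expressed in W m$^{-2}$: canopies absorb
near-infrared much less efficiently than PAR, and midday longwave loss
offsets most of the remainder, so a multiplier near one reproduces
realistic daily transpiration totals. Both are exposed as arguments.

Chamber geometry defaults (`system_config()`) follow a cylindrical
0.3 m$^3$ chamber over a 0.2 m$^2$ footprint with a regulated volumetric
flow of 4.3×10$^{-3}$ m$^3$ s$^{-1}$ (one air change every ~70 s),
converted to molar units by the ideal gas law at 25 °C — the conversion
temperature is configurable because loggers report volumetric flow.

## The synthetic-data module

No chamber logs or canopy samplings are bundled; `generate_weather()`,
`simulate_chamber_series()`, `generate_canopy_profile()` and
`generate_night_respiration()` create them with known ground truth.
The weather generator produces a clear mid-summer day at a mid-latitude
site: PAR follows solar elevation scaled to a 2,100 µmol m$^{-2}$ s$^{-1}$
peak, temperature (17.6–35.9 °C), vapour pressure (1.7–2.5 kPa) and CO$_2$
(359.7–439.4 µmol mol$^{-1}$, mirrored) follow lagged sinusoids. The
chamber simulator inverts the flux equations exactly, so noiseless logs
round-trip to machine precision; noise is additive Gaussian on the logger
differentials, mimicking analyser error, with magnitudes configurable
because instrument noise levels are site-specific rather than published
values. `chamber_microclimate()` derives in-chamber weather from a
steady-state mass balance — CO$_2$ drawn down by $A_{c,net}a/u_e$, vapour
pressure raised by the transpiration differential — applying half the
exit differential (the canopy sits between entrance and exit air) plus a
configurable radiative warming (default 4 °C at full sun). By default the
radiation input is *not* attenuated by wall transmittance: the radiation
sensor of the emulated system sits outside the chamber, and the small
simulated photosynthesis effect of enclosure is consistent only with the
same radiation record driving both simulations. A switch restores the
attenuated alternative.

What the generators do not emulate: broken cloud (weather is smooth),
within-day weather fronts, sensor drift (noise is white), soil-moisture
dynamics (water supply is an imposed allowance), and leaf-angle or
senescence dynamics (the canopy is static within a day). Passing tests
therefore demonstrate the correctness of the arithmetic, fits and model
structure under controlled conditions — not the field validity of the
parameter values, which must come from measurements.

## Numerical choices

- **Coupled leaf solution.** The stomatal/diffusion/biochemistry system
  is solved by bracketed root finding on $C_i$ (tolerance 10$^{-9}$),
  with a coarse-grid fallback for degenerate corners. Tests verify the
  returned operating point satisfies all three equations independently.
- **Leaf temperature** is solved by damped fixed-point iteration of the
  energy balance (tolerance 0.01 °C, max 25 iterations, step clipped to
  ±10 °C); `leaf_temp = "air"` bypasses it.
- **Boundary-layer resistances** use the flat-leaf forced-convection
  form $r_{bh} = 1/(0.01\sqrt{u/w})$ per unit leaf area, divided by the
  fraction's LAI; $r_{bw} = r_{bh}/0.93$.
- **kn → 0 limit.** The cumulative-nitrogen model is evaluated through
  `expm1` with a series expansion below $k_n LAI < 10^{-12}$, keeping
  the model and its Jacobian smooth where a uniform profile puts the
  optimum on the $k_n = 0$ boundary; the fit runs Levenberg–Marquardt on
  raw residuals with standard errors from an absolute-step Jacobian,
  because relative-step derivatives degenerate at that boundary.
- **QC filtering** flags records whose entrance CO$_2$ or vapour pressure
  deviates from a 7-record rolling median by more than 4 robust standard
  deviations. The robust scale is estimated from the *non-zero*
  residuals (in slope-dominated stretches the centre record is its own
  window median, which zero-inflates the residuals), and the threshold
  never falls below small absolute floors (1 µmol mol$^{-1}$,
  0.02 kPa) so the curvature of a smooth noiseless diurnal course is
  never flagged.
- **Night handling.** Records with PAR < 5 µmol m$^{-2}$ s$^{-1}$ count
  as night; nightly correction factors are forced to 1; a residual
  stomatal conductance `g0` keeps Penman–Monteith defined in the dark;
  gross photosynthesis is defined as zero at night.
- **Daily integration** is trapezoidal with gaps longer than 3 cadence
  steps left unbridged and reported through a coverage fraction.
- **Forcing semantics.** In `forcing_analysis()` the forced trait is
  LAI or *mean* SLN — the quantities treatment tables report — while the
  profile-shape coefficient $k_n$ stays with the canopy whose size it
  belongs to, and $SLN_0$ is re-derived from the intended mean. Copying
  a small canopy's steep $k_n$ onto a large one would conflate the
  nitrogen *amount* being forced with an unintended profile change.

## Design choices that were genuinely open

- **Which nitrogen equation to fit.** The cumulative integral (fit on
  $N_i$–$LAI_i$) is the primary route because cumulative N is what the
  layered destructive sampling measures most robustly; fitting the
  per-layer $SLN_i$ decline directly is available via `on = "sln"`.
- **Volumetric-to-molar flow conversion** is done at a configurable
  temperature (default 25 °C); whether a given system regulates flow at
  ambient or chamber temperature is a property of the installation.
- **Treatment averaging.** `compute_efficiencies()` computes ratios per
  chamber-day; averaging those (rather than taking ratios of averages)
  is the default because it weights days equally, and the alternative is
  a one-line summarise on the same output.
- **Percent-change conventions.** Published treatment contrasts divide
  sometimes by the larger value and sometimes by the control; both
  conventions are first-class (`percent_change()`), tagged explicitly,
  because silently mixing them changes headline numbers by tens of
  percent.

## Problem sizes used by the test-suite

Simulations run at 12-min cadence over one day (120 records); Monte-Carlo
checks use 100 replicates (fits on 500 night records or 4-layer
profiles); the sun/shade-vs-multilayer comparison integrates 200 layers
over a 5 × 5 grid of LAI and PAR. These sizes keep the full suite under a
few minutes while leaving the stochastic checks well-powered.

## Known limitations

- The radiation proxy ignores the longwave balance explicitly; under
  strongly advective or overcast conditions `rn_par_mult` needs
  re-estimation.
- Water-limited photosynthesis reuses the potential-mode leaf
  temperature; under severe stress the true leaf would be warmer.
- The two-big-leaf aggregation is verified to within 5 % of a 200-layer
  integration for LAI ≤ 6 and midday sun; errors grow at very low solar
  elevation, where absolute fluxes are small.
- Respiration is a single canopy-level pool with one temperature
  response; no growth/maintenance split, no acclimation.
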