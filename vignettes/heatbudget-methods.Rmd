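---
title: "Methods: indices, the energy-budget model, and the synthetic sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: indices, the energy-budget model, and the synthetic sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatbudget)
```

## The problem

Exertional heat illness is a leading cause of death and disability in youth
sport, and American football — played in pads, on synthetic turf, in late
summer — is the highest-risk setting.  The two instruments most often used
to decide whether practice is safe, the National Weather Service heat index
(HI) and the wet bulb globe temperature (WBGT), were both developed for
adults at moderate activity and ignore most of the microclimate: the
radiant load from a 60 °C turf surface, the sky view, shade, clothing, and
the physiology of a child.  This package implements all three estimates —
HI, WBGT, and a COMFA-style human energy budget with child and adult
parameterizations — on a shared five-level category scale, so their
disagreement on the same afternoon can be quantified.

## The three methods

**Heat index.**  `heat_index()` follows the NWS practical procedure.  Air
temperature is converted to °F; the simple averaged formula
$0.5\,[T + 61 + 1.2(T-68) + 0.094\,RH]$ is evaluated first, and when the
mean of that value and $T$ reaches 80 °F the full Rothfusz regression
replaces it, with the NWS low-humidity ($RH<13\,\%$, 80–112 °F) and
high-humidity ($RH>85\,\%$, 80–87 °F) adjustments.  The canonical
regression coefficients are used.  The procedure is only approximately
continuous at the branch hand-off: scanning the 75–85 °F band we record a
maximum jump of about 2.1 °F (at RH 80 %), which is inherent to the NWS
two-formula design, not to this implementation.

**Wet bulb globe temperature.**  `wbgt()` is the ISO 7243 outdoor
weighting $0.7\,T_w + 0.2\,T_g + 0.1\,T_a$.  One published transcription
of this formula carries a stray sign on the globe term; we use $+0.2$,
since the weights of a convex combination must sum to one and a hotter
globe cannot lower the index.  The natural wet-bulb temperature comes from
Stull's (2011) empirical closed form in `wet_bulb_stull()`, evaluated
exactly as printed (arctangents in radians, RH in percent).  Two numerical
properties of that fit matter and are asserted in the test suite at their
true magnitudes:

* against an iterative psychrometric-balance oracle (adiabatic saturation
  with Bolton's saturation curve and temperature-dependent latent heat)
  the mean absolute error over $T_a \in [5,45]$ °C, $RH \in [5,99]\,\%$ is
  ≈ 0.32 °C, but the worst corner (hot and very dry) reaches ≈ 1.1 °C —
  consistent with the fit's published accuracy, whose mean error is near
  0.3 °C with extremes near 1 °C;
* the physical bound $T_w \le T_a$ is violated by ≈ 0.01 °C at the single
  hot-saturated corner (45 °C, 99 %), so bound checks carry a 0.02 °C fit
  tolerance.

`wbgt_from_weather()` requires a measured black-globe column and refuses
to substitute a model for it; the only globe closure in the package lives
in the synthetic generator, where it is explicitly scaffolding.

**Energy budget.**  The budget per unit body surface area is

$$B \;=\; M + R_{abs} - C - E - L_{emit} \quad [\mathrm{W\,m^{-2}}]$$

computed by `energy_budget()` as a series resistance network.  The five
streams are metabolic heat, absorbed short- and longwave radiation,
sensible convection, evaporation, and emitted longwave.  A sustained
surplus marks heat stress; the five-level scale cuts at 60, 120, 200 and
340 W m⁻².

## Closures and constants

Only the budget's structure and the physiological anchors (RMR 52 vs
42 W m⁻², MET 7 vs 4, half sweat capacity for the child, WHO-median
anthropometry) are fixed by the study design the package reproduces; the
internal closures are this package's own, and every constant lives in
`heat_constants()` so a run can be recalibrated without code changes:

* **Metabolism and core temperature.** $M = \mathrm{MET}\times
  \mathrm{RMR}$; $T_c = 36.5 + 0.0043\,M$ °C supplies the driving
  gradient.  A child playing football runs $M = 364$ W m⁻².
* **Resistances** (s m⁻¹): clothing $r_c = \mathrm{clo}\times 0.155\,
  \rho c_p$; aerodynamic $r_a = \rho c_p\, d /(\mathrm{Nu}\, k_{air})$
  treating the body as a cylinder of diameter $d = \mathrm{BSA}/(\pi h)$
  in cross-flow with Hilpert's $\mathrm{Nu}(\mathrm{Re})$ bands and a
  0.3 m s⁻¹ wind floor (the forced-convection correlation degenerates in
  a calm); tissue $r_t = \mathrm{clamp}(104 - 0.25\,M,\ 10,\ 104)$,
  vasodilating with activity.  Skin and clothing-surface temperatures are
  read off the same network, so convection, evaporation and emission are
  mutually consistent.
* **Radiation.** Global irradiance splits into beam and diffuse by the
  site's diffuse fraction (clear-sky default 0.15); the beam is
  intercepted by a vertical cylinder, $f_{cyl} = \cos\beta/\pi$; sky
  diffuse is weighted by half the sky view factor; ground reflection by
  half the ground albedo; canopy shade attenuates the beam and sky terms
  only.  Longwave uses Idso's clear-sky emissivity for the sky half-view
  and the ground surface temperature for the lower half-view.  Solar
  elevation $\beta$ comes per record from the series, or from NOAA-style
  solar geometry given a timestamp and coordinates.
* **Evaporation.** Tetens psychrometrics give the potential flux
  $E_{pot} = (\rho c_p/\gamma)\,[e_s(T_{sk}) - e_{air}]/(r_a + r_{cv})$;
  skin wettedness ramps linearly from 0.06 at rest to 1 at
  $M = 400$ W m⁻²; the result is capped at the sweat capacity, 365 W m⁻²
  for an adult and half that for a child.  The clothing vapour resistance
  $r_{cv} = 150$ s m⁻¹ was chosen so that the child athlete at the hot
  session mean produces $w\,E_{pot} \approx 282$ W m⁻² — comfortably
  above the child cap, which is the behaviour the parameterization is
  anchored to.

With the default registry the May-mean single point (Ta 33.3 °C, RH 48 %,
Ws 2.4 m s⁻¹, SR 886.8 W m⁻², turf at 60 °C, sun at 60°) gives the child
athlete $B \approx 361$ W m⁻² (Extreme Danger), the coach on grass
$\approx 199$ W m⁻² and the seated, shaded parent $\approx 73$ W m⁻² —
the one-to-two-category spread between field and sideline that motivates
carrying a child-specific model at all.  The 60° reference elevation is a
representative early-afternoon value used for single-point checks; full
scenario runs use per-record elevations.

A documented limitation: the budget is monotone in radiation, surface
temperature and shade everywhere on the tested grid, and monotone in MET
in calm-to-moderate wind, but in strong dry wind (≈ 6 m s⁻¹) the
wettedness ramp lets evaporative cooling briefly outpace added metabolic
heat, so the budget is only locally monotone in MET there.  The study
sessions sit well inside the monotone regime.

## Categories, agreement, and the band mapping

All three methods map onto ordinal levels 0–4 via half-open bins
(`classify_heat()`).  Published threshold tables print small gaps
(e.g. HI 31.7 → 32.2) and one overlap in the WBGT column; we anchor each
bin at the lower bound of the printed upper category and resolve the WBGT
overlap at 32.4 °C with the more-severe-category-wins rule — totality and
monotonicity are non-negotiable for a classifier, and the printed gaps
are rounding artifacts.  One consequence: a value sitting exactly on a
printed *upper* edge (EB = 120 W m⁻²) classifies into the more severe
bin.  `eb_to_hi_band()` derives the energy-budget-to-heat-index band
correspondence (after Harlan et al.) from the same bins, so the two can
never disagree.  `agreement_pct()` is the fraction of timesteps with
identical level — meaningful precisely because all methods share the
ordinal scale — and `time_in_category()` and `category_range()` produce
the standard session summaries.

## The synthetic sessions

No raw field series is distributed, so `generate_micromet()` draws
seeded, reproducible sessions that emulate two reported mid-day sessions
on a Texas artificial-turf field: a two-hour late-May window (means
Ta 33.3 °C, RH 48 %, Ws 2.4 m s⁻¹, SR 886.8 W m⁻²) and a one-hour
early-October window (34.0, 42.9, 4.04, 574.3), both at 10-s cadence
(720 and 360 records).  Radiation follows clear-sky geometry
$S_0 \sin\beta\, \tau^{1/\sin\beta}$ with $\tau$ solved once per session
so the deterministic window mean hits the session mean; temperature is a
diurnal sinusoid recentred on the window mean plus AR(1) noise; humidity
is anti-correlated with the temperature anomaly (−2.5 % per °C, the
constant-dewpoint slope at these conditions) and clipped to [5, 99] %
with clips counted in the metadata; wind is mean-preserving lognormal
AR(1).  The globe and turf-surface closures
$T_g = T_a + c_1 SR/(1+c_2 W_s)$ and
$T_s = T_a + c_3 SR(1-\alpha_{turf})/(1+c_4 W_s)$ use $c_1 = 0.02$,
$c_2 = 0.7$, $c_3 = 0.06$, $c_4 = 0.5$, $\alpha_{turf} = 0.08$, chosen so
midday globe excess is 5–15 °C and turf runs ≈ 55–70 °C under the May
forcing — magnitudes consistent with field reports for synthetic
surfaces.  These closures are test scaffolding with plausible physics,
not measurement models.

What the generator does **not** emulate: clouds, precipitation, multi-day
structure, instrument error, and the sub-minute intermittency of real
turbulence.  Tests that pass on synthetic sessions therefore validate the
pipeline's arithmetic, orderings and calibration contracts — not the
field accuracy of any closure.

```{r, fig.width = 6, fig.height = 4}
defs <- study_defaults()
s <- generate_micromet(may_session_spec(seed = 1))
run <- run_scenario(s, defs$scenarios$athlete)
plot(run)
```

## Numerical choices and degenerate inputs

* Timestamps must be strictly increasing; duplicates are errors, never
  resampled away.  Optional columns are all-present or all-absent;
  downstream consumers fail loudly instead of imputing.
* All temperatures are carried in °C; °F exists only inside the
  heat-index regression and in explicit conversions.
* Beam normal irradiance divides by $\max(\sin\beta, 0.05)$ and a solar
  elevation ≤ 2° with SR > 50 W m⁻² raises an inconsistency warning.
* Session aggregates are reported at one decimal, matching how such
  campaigns print their tables; full precision is preserved in CSV.
* Problem sizes in the test suite: index property grids of ~10³ points,
  a 10⁴-point conservation sweep, and the two bundled sessions (720 and
  360 records) — sizes at which every property is exercised in seconds.

## Known limitations

Steady-state only: no transient heat storage, no acclimatization, no
child skin-temperature offset (reported qualitatively in the physiology
literature but without a printed closure, so deliberately not guessed).
The child/adult contrast enters entirely through the profile (RMR, MET,
anthropometry, sweat capacity); if a future calibration wants the often
quoted ≈ 408 W m⁻² for a boy playing football rather than
7 × 52 = 364 W m⁻², that is a registry/profile adjustment, not a code
change.
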