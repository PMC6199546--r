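---
title: "Methods: ensemble green-water forecasting and its verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble green-water forecasting and its verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Seasonal weather forecasts are issued as ensembles: one unperturbed
*control run* (CR) and N perturbed members, each an equally probable
realization of the coming growing season. Pushing every member through a
water-driven crop model turns the weather ensemble into an ensemble of
*crop model outputs* — growing-season precipitation, accumulated crop
evapotranspiration (ET), yield — and of the derived green-water
indicators: the green water footprint (GWF, m³ of evapotranspired
rain-fed water per tonne of yield) and water productivity for yield
(WPet, kg of yield per m³ of ET). The question the verification layer
answers is whether that ensemble of estimates behaves like the
distribution from which the observation-based outcome (OB, the same crop
model driven by observed weather) is drawn.

`greencast` implements this chain end to end with two deliberate
substitutions that make it testable on a desk: a seeded stochastic
weather generator stands in for an operational seasonal ensemble plus
station records, and a compact soil-water-bucket crop surrogate stands in
for a full crop model. Both are first-class, tested components, and both
are honest about what they do not reproduce (see *Limitations*).

## Synthetic weather generator

One season is the fixed window 1 March – 1 October. The window always
contains 215 days and never contains 29 February, so leap years need no
special handling.

**Temperature.** Daily mean temperature is an annual cosine cycle
(`temp_mean` ± `temp_amplitude`, warmest at `temp_phase_doy`) plus AR(1)
noise with lag-1 autocorrelation `temp_autocorr` and stationary standard
deviation `temp_noise_sd`; a fixed `diurnal_range` splits it into
tmax/tmin. Defaults (11.5 °C mean, 11 °C amplitude, 2 °C noise, 0.6
autocorrelation) emulate a moderate-continental Pannonian-plain station.

**Precipitation.** Occurrence is a two-state Markov chain with
dry-to-wet probability `p01` and wet-to-wet `p11`, started at its
stationary wet-day frequency `p01/(1 + p01 − p11)`; wet-day amounts are
gamma(`gamma_shape`, `gamma_scale`). The defaults (0.25/0.55, gamma
0.8 × 6 mm) give ≈36 % wet days and ≈630 mm/yr, with realistic dry/wet
spell clustering.

**Radiation.** A sunshine fraction is sampled (normal around
`sunshine_mean`, damped by `wet_day_sunshine_factor` on wet days,
clipped to [0, 1]) and converted to global radiation through the
Angstrom–Prescott relation `Rs = (a + b·n/N)·Ra` with extraterrestrial
radiation `Ra` from the standard solar-geometry closed form. The
coefficients default to a = 0.25, b = 0.50, the conventional values in
the absence of a local calibration. Humidity and wind are clipped
Gaussian noise: they are carried for schema completeness but unused by
the surrogate's temperature/radiation ET₀.

**Ensemble emulation.** The control run applies only the systematic
biases (`member_temp_bias` additive, `member_precip_bias`
multiplicative). Each member adds independent noise scaled by one knob,
`member_inflation`: an additive temperature perturbation (the same draw
on tmax and tmin, so the diurnal range and the tmax ≥ tmin invariant are
preserved by construction), a mean-one lognormal factor on wet-day
amounts, and day-wise occurrence decoupling — with probability
`min(1, inflation × decoupling)` a member day's wet/dry state is drawn
from its own Markov chain conditioned on the member's previous day,
otherwise it copies the truth. This blend keeps Markov-like spell
statistics at every decoupling level, reproduces the truth exactly at
inflation 0, and approaches a fully independent season at high
inflation. Ensemble size is configured per year; the bundled default
ramp rises from 10 members in 2006 to 50 in 2014, mirroring the growth
of operational seasonal systems over that period.

**Seeding.** A master seed spawns per-(site, year, stage) sub-streams
through a deterministic string-hash (`derive_seed`), and every sampling
routine restores the caller's RNG state. Members are drawn *jointly*
(vectorised across the ensemble inside the day loop) from the year's
ensemble stream: reproducibility is guaranteed for a fixed
(config, seed, N). We chose joint drawing over per-member sub-streams —
under which adding a member would leave existing members unchanged —
because the sequential occurrence chain would otherwise cost one scalar
R iteration per member-day, two orders of magnitude slower, which
matters for the large calibration simulations below.

## Crop surrogate

The surrogate keeps the core identity of water-driven crop models
(biomass = WP\* · Σ Tr/ET₀; yield = HI · biomass) and the daily
soil-water bucket, and drops everything else (canopy-cover dynamics,
stress effects on HI, CO₂ response, fertility). Per day from planting:

* Phenology: GDD = max(0, (Tmax+Tmin)/2 − Tbase) accumulates; the season
  ends at the GDD requirement (matured) or at 1 October (cut off),
  whichever comes first; `lgp` is the realized length in days.
* Canopy: a piecewise-constant basal coefficient Kcb over four stages
  switching at fixed fractions of the GDD requirement.
* Water: TAW = (fc − wp) · root depth · 1000 mm; RAW = p · TAW; the
  stress coefficient Ks is 1 while depletion ≤ RAW and falls linearly to
  0 at TAW. Transpiration Tr = Ks·Kcb·ET₀; soil evaporation
  E = Ke·ET₀·(1 − Kcb/max Kcb), using Kcb/max Kcb as a canopy-fraction
  proxy. Both fluxes are jointly rescaled so the bucket never goes
  negative; water above TAW leaves as a single drainage/runoff overflow
  term — the simplest closure that conserves water exactly, which the
  tests verify to 10⁻⁶ mm per season.
* ET₀ is Hargreaves (temperature + extraterrestrial radiation) because
  those are the variables the generator makes realistic; an `et0` column
  on the weather series overrides it day by day, which is both the
  plug-point for Penman–Monteith-style inputs and the lever the
  hand-stepped unit tests use.
* Units: internal mm and t/ha; the g/m² → t/ha factor is fixed at 0.01.

The bundled crop parameter files (maize, spring barley, sunflower) and
the two site files are *synthetic* illustrative sets drawn from standard
crop-water-literature ranges — the `_synthetic` suffix in their names is
deliberate — because the corresponding calibration tables of the source
material are not machine-readable. They produce agronomically plausible
magnitudes (e.g. maize ≈10–12 t/ha, ET ≈350–450 mm under the default
climate) but are not a calibration of any real station.

## Green-water indicators

GWF = 10 · ΣET/Y (m³/t; the factor 10 converts mm over one hectare to
m³, kept as one named constant) and WPet = 100 · Y/ΣET (kg/m³). Under
these yield-based definitions WPet·GWF = 1000 kg/t exactly, which is
enforced as an invariant test rather than assumed. A zero-yield season
makes GWF undefined: the package raises/flags it and the pipeline drops
such members from verification with a logged warning — crop failure is
reported, never imputed.

## Verification conventions

Per year, over the N member values Yᵢ of one variable:
RMSE = √(1/N · Σ(Yᵢ − Y^OB)²) and SPRD = √(1/N · Σ(Yᵢ − Y^EA)²) with
Y^EA the member mean. The 1/N (population) divisor is the default for
both because it makes the decomposition
RMSE² = SPRD² + (Y^EA − Y^OB)² exact, which doubles as the
implementation's own oracle; a sample (N−1) variant sits behind a flag.
An ideal ensemble has RMSE = SPRD, i.e. zero ensemble-average error.

For a statistically calibrated ensemble the spread–skill relation takes
the form E[(Y^EA − Y^OB)²] = (1 + 1/N) · E[s²] with s the
*sample-convention* spread; the property tests check exactly this form.

The realism criteria after Pielke are inherently multi-year: (a) the
simulation RMSE is below the standard deviation of the observed values,
σ_OB, and (b) the simulated σ is "close to" σ_OB. "Close" is undefined
in the source tradition, so it is made explicit and configurable as a
ratio band (default within a factor 2). The multi-year summary applies
(a)/(b) to the cross-year RMSE and σ of the CR and EA series; the
per-year report additionally evaluates the year's RMSE and SPRD against
the multi-year σ_OB as an indicative per-year flag. Multi-year mean, σ
and cv use the sample (N−1) convention, since the years are a sample.
Years that cannot be verified (missing OB, fewer than two members) are
skipped with a logged warning, never imputed.

## Ignorance score

The ensemble is turned into a probabilistic forecast by a Gaussian fit:
μ = member mean, σ = member standard deviation (population convention,
matching the spread; configurable), screened for normality with a
Shapiro–Wilk test at α = 0.05 (the screening test is not dictated by the
source tradition; Shapiro–Wilk is the standard omnibus choice at
ensemble sizes 10–50). Years failing the screen are flagged and excluded
from score summaries, not scored as if Gaussian.

The observation is standardized, Z = (Y^OB − μ)/σ, and scored against
the standard Gaussian density:

S = −log₂ φ(Z) = ½·log₂(2π) + Z²/(2 ln 2)  bits,

with minimum ≈1.3257 bits at Z = 0. Standardization makes scores
comparable across variables; the raw-density variant S + log₂σ is
available behind a flag. The interpretation thresholds are the boundary
scores at one and three standard deviations: −log₂ φ(1) ≈ 2.047
(printed as 2.04 in the applied literature) and −log₂ φ(3) ≈ 7.818
(printed 7.81); categorisation uses the printed values for
comparability, while `ignorance_thresholds()` also exposes the analytic
forms and the analytic exceedance probabilities (0.68 below 2.04, 0.954
below 4.21, 0.0027 above 7.81 — the package reports these analytic
values; some published roundings of the middle two differ). A high mean
score with low score-sd over years flags the chosen distribution as
inadequate; high mean with high sd flags a systematic disruption of the
forecast or the simulation; the two thresholds (default 4.21 and 2.0
bits) are explicit parameters since the tradition states the rule only
qualitatively.

## Numerical and testing choices

* Degenerate inputs: all-identical members give a degenerate Gaussian
  (error, never a silent 0-bit score); zero-ET days skip the biomass
  increment; zero-yield seasons propagate as flagged NA indicators.
* The calibrated-score recovery test generates ensembles with the
  weather generator at zero bias, fits the Gaussian to member
  season-precipitation totals and draws the verifying observation from
  the fitted predictive density; then E[S] = ½log₂(2π) + 1/(2 ln 2) ≈
  2.047 bits exactly, independent of ensemble size. Problem sizes: 10⁴
  simulated years (Monte-Carlo s.e. ≈0.01 bits) for the ±0.05 check, and
  3000 years per bias level {0, 0.5σ, 1σ, 2σ} for monotonicity, where
  the smallest expected separation (≈0.18 bits) is ≥3 Monte-Carlo
  standard errors.
* The Markov stationary frequency, the analytic season-precipitation
  expectation, the RMSE²-decomposition (1000 random ensembles) and the
  WPet·GWF identity (1000 random pairs) are property tests with fixed
  seeds.
* Multi-year verification in the bundled experiments uses 2–3 seasons ×
  5–10 members — deliberately small, as the statistics under test are
  exact identities or seeded expectations, not asymptotics.

## What passing tests do and do not show

The generator reproduces the *statistical* structure a verification
layer needs — seasonal cycle, spell statistics, configurable bias and
spread regimes with known truth — but not weather fronts, heat waves,
dry-spell persistence beyond first-order Markov, or temperature–
precipitation cross-correlation. The surrogate responds to water
limitation and phenology-driven season length (warmer members mature
earlier) but not to heat sterility, fertility or pest stress. Passing
verification here therefore demonstrates the correctness of the
forecasting/verification machinery, not the skill of any real seasonal
forecast system for a real site; conclusions about real crops require
re-running the verification layer (`verify_from_table()`) on outcomes
from a calibrated crop model driven by genuine forecasts.
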