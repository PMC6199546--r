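# greencast

Probabilistic seasonal forecasting of crop yield and green-water
indicators, with ensemble verification.

Seasonal weather forecasts come as ensembles — a control run (CR) plus N
perturbed members, each an equally likely realization of the coming
growing season. `greencast` pushes every member through a water-driven
crop surrogate to obtain ensembles of season precipitation, crop
evapotranspiration (ET), yield, and the derived green-water indicators,
and then verifies those ensembles against the observation-based outcome
(OB, the same model driven by observed weather):

- **Green water footprint** `GWF = 10 · ΣET / Y` (m³ of evapotranspired
  rain-fed water per tonne of yield) and **water productivity**
  `WPet = 100 · Y / ΣET` (kg/m³), linked by the exact identity
  `WPet · GWF = 1000`.
- **Ensemble statistics** per year over N members:
  `RMSE = sqrt(mean((Yᵢ − Y_OB)²))`, spread
  `SPRD = sqrt(mean((Yᵢ − Y_EA)²))` around the ensemble average, with
  the exact decomposition `RMSE² = SPRD² + (Y_EA − Y_OB)²`; multi-year
  realism checks after Pielke (RMSE below the observed variability, and
  simulated variability close to observed).
- **Ignorance score** of the Gaussian predictive density fitted to the
  members: `S = −log₂ φ(z)` bits at the standardized observation
  `z = (Y_OB − μ)/σ`, with interpretation boundaries 2.04 bits (|z| = 1,
  very good), 4.21 bits (|z| = 2, acceptable) and 7.81 bits (|z| = 3,
  not adequate), after a Shapiro–Wilk normality screen.

Because real seasonal-forecast archives and station records cannot ship
with a package, `greencast` includes a seeded stochastic weather
generator (seasonal temperature cycle + AR(1) noise, two-state Markov /
gamma precipitation, Angstrom–Prescott radiation, Hargreaves ET₀) whose
ensemble emulation has controllable bias and spread, and a compact
AquaCrop-style surrogate (GDD phenology, daily soil-water bucket,
Ks-stressed transpiration, normalized-water-productivity biomass,
harvest-index yield). Both are documented in the methods vignette
(`vignettes/greencast-methods.Rmd`), including what they deliberately do
not reproduce. Intended audience: agro-hydrologists and forecast
verification researchers who want the verification machinery with a
controllable, fully reproducible testbed.

## Worked example

```r
library(greencast)

cfg   <- climate_config()                 # synthetic Pannonian-plain climate
truth <- generate_truth(cfg, year = 2010, seed = 42)       # "observed" season
ens   <- perturb_members(truth, n_members = 10, config = cfg, seed = 42)

crop <- read_crop_params(system.file("extdata/crops/maize_synthetic.yaml",
                                     package = "greencast"))
soil <- read_soil_params(system.file("extdata/sites/pannonia_south_synthetic.yaml",
                                     package = "greencast"))

res <- run_season(truth, crop, soil)      # observation-based outcome
res
#> <season_result> maize [OB]: lgp 160 d (matured), precip 317.3 mm, ET 405.2 mm, yield 12.62 t/ha
water_indicators(res)
#>     precip       et    yield      gwf     wpet
#> 1 317.3066 405.1851 12.61668 321.1503 3.113807

yields <- vapply(ens$members, function(w) run_season(w, crop, soil)$yield,
                 numeric(1))
out <- ensemble_outcome(2010, "pannonia_south", "maize", "yield", yields,
                        observed = res$yield)
out
#> <ensemble_outcome> 2010 pannonia_south/maize yield: N=10, EA=11.75, CR=NA, OB=12.62

ignorance_score(res$yield, fit_gaussian(yields))
#> <ignorance_result> z +0.628, S 1.610 bits (very_good)
```

The full multi-site, multi-year, multi-crop pipeline is one call:
`run_experiment(experiment_config(sites, crops, years, seed))` writes
`outcomes.csv`, per-year and multi-year verification tables, ignorance
scores and summaries, and a reproducibility manifest; the same pipeline
is scriptable via `inst/scripts/greencast.R` (`simulate` / `verify`
subcommands). `verify_from_table()` runs the verification layer on any
externally produced outcome table with the same columns.

## Layout

- `R/` — generator (`weather_gen.R`), surrogate (`crop_model.R`),
  indicators (`green_water.R`), verification (`verification.R`),
  ignorance (`ignorance.R`), pipeline (`pipeline.R`)
- `inst/extdata/` — synthetic crop and site parameter files (YAML;
  illustrative, not a calibration of real stations)
- `inst/scripts/greencast.R` — command-line interface
- `vignettes/greencast-methods.Rmd` — methods, conventions, limitations
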