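Package: greencast
Title: Probabilistic Seasonal Forecasting and Verification of Green Water
    Use and Crop Yield
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ensemble-based seasonal forecasting of green water
    components (growing-season precipitation, evapotranspiration), crop
    yield, green water footprint and water productivity of rainfed summer
    crops. Provides a seeded stochastic weather generator emulating a
    seasonal ensemble prediction system (truth, control run and perturbed
    members), a water-driven crop simulation surrogate with growing
    degree-day phenology, a daily soil water bucket and normalized
    water-productivity biomass accumulation, derived green water
    indicators, and a verification layer with per-year ensemble RMSE and
    spread, skill criteria, Gaussian-fit Ignorance scores under Z-score
    standardization, and multi-year summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
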