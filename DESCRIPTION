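Package: heatbudget
Title: Heat-Stress Indices and Human Energy Budgets for Outdoor Youth Sport
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes and compares three estimates of heat stress at outdoor
    sports venues from micrometeorological time series: the National Weather
    Service heat index, the wet bulb globe temperature (with natural wet-bulb
    temperature from Stull's empirical formula), and a COMFA-style human
    energy budget with separate child and adult physiological
    parameterizations.  Each estimate is mapped to a common five-level
    heat-stress category scale so methods can be compared by time-in-category
    and inter-method agreement.  Includes a seeded synthetic weather generator
    that emulates mid-day field sessions on artificial turf, persona/site
    presets (a child athlete on turf, a coach on grass, a seated parent in
    tree shade), and scenario orchestration that produces per-timestep tables,
    summaries and agreement matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
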