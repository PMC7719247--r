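Package: soccost
Title: Marginal Cost Curves for Soil Organic Carbon Sequestration from
    No-Till Adoption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates soil organic carbon (SOC) stock changes on cropland
    from tillage-intensity transitions using the IPCC Tier-1 factor method
    (reference stocks multiplied by climate-dependent land-use, management
    and input factors, with linear approach to a new equilibrium over 20
    years), prices each land stratum's sequestration with conservation
    program payments, and assembles marginal cost curves for CO2
    sequestration with threshold queries, sequence and region summaries,
    and a seeded synthetic strata generator for fully reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
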