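Package: rothcgrass
Title: RothC Soil Organic Carbon Turnover for Temperate Managed Grasslands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monthly five-pool RothC-26.3 soil organic carbon turnover
    simulation extended for temperate moist managed grasslands: a soil
    moisture rate-modifying factor extended beyond field capacity to
    saturation, partitioning of ruminant excreta carbon into model entry
    pools from Van Soest fibre fractions, three-component plant residue
    inputs (above-ground, below-ground, rhizodeposition) with
    fibre-based quality, and a parametric livestock poaching (trampling)
    effect on wet soils. Modifications can be enabled individually or
    through the cumulative version ladder RothC_0 to RothC_4. Includes
    pool initialisation from measured stocks, model evaluation
    statistics (RMSE, BIAS, model efficiency), one-at-a-time sensitivity
    sweeps and a seeded synthetic-site generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
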