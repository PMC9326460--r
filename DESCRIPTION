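Package: heni
Title: Dietary Human-Health Impact Characterization for Food Life Cycle Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies dietary-risk-component inventory flows (grams per
    functional unit) from recipe composition tables, characterizes them with
    Dietary Risk Factors (microDALY per gram) into disability-adjusted life
    year impacts and the Health Nutrient Index (minutes of healthy life
    gained or lost per serving, per 100 g, or per kcal), derives Dietary
    Risk Factors from epidemiological primitives (relative-risk curves,
    theoretical-minimum-risk exposure levels, intake distributions and
    burden rates) via comparative risk assessment, evaluates non-marginal
    diet scenarios with multiplicative attributable-fraction combination,
    and sums dietary with environmental damage-level impacts while keeping
    track of contributions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'registry.R'
    'AllClasses.R'
    'AllGenerics.R'
    'composition.R'
    'characterization.R'
    'epi-curves.R'
    'epi-drf.R'
    'scenarios.R'
    'io.R'
    'fixtures.R'
    'synthetic.R'
    'cli.R'
    'heni-package.R'
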