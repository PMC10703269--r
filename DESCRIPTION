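Package: codtdf
Title: Trophic Discrimination Factors and Bioenergetics for Juvenile
    Pacific Cod Feeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing controlled feeding trials that estimate
    carbon and nitrogen stable-isotope trophic discrimination factors
    (TDFs) in juvenile fish under crossed diet and temperature
    treatments.  Includes a synthetic-trial generator with known ground
    truth, lipid normalization of delta-13C from C:N ratios using the
    marine-fish closed-form correction, per-treatment TDF estimation
    with pooled and equal-weight summaries, a consumption to
    assimilation to retention mass budget with regression interpolation
    of mass and body composition, and linear mixed-effects treatment
    comparison with AIC model selection and Tukey-adjusted compact
    letter displays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    emmeans,
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
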