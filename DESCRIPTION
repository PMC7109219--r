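Package: vitalink
Title: Birth-Death Record Linkage and Infant Mortality Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking infant death registrations to hospital birth
    records and estimating infant mortality rates from the resulting period
    linked file. Provides a synthetic registry generator with ground truth
    (Ontario-style hospital birth cohorts with configurable corruption), a
    deterministic identifier pass followed by Fellegi-Sunter probabilistic
    linkage with EM-estimated match parameters, and a mortality-rates engine:
    crude, neonatal and post-neonatal rates, birthweight- and gestational
    age-specific rates, stratified rates, modified ICE cause-of-death
    groupings, exact binomial (Clopper-Pearson) confidence intervals and
    small-numerator suppression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
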