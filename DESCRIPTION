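Package: obdecomp
Title: Oaxaca-Blinder Decomposition of Urban-Rural Gaps in Binary Health Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the gap in a binary health outcome (institutional
    delivery) between two population groups (urban and rural women) into
    explained (endowment) and unexplained (coefficient) components using the
    Oaxaca, Blinder, Reimers and Cotton weighting schemes for non-linear
    (logit/probit) and linear models, with a Heckman two-step selection
    correction via the inverse Mills ratio, a Yun-style detailed decomposition
    of the explained component across covariate groups, stratified bootstrap
    inference for all components, and a calibrated synthetic survey generator
    emulating Demographic and Health Survey birth records for validation and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
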