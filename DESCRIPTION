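Package: paleocvd
Title: Climate Predictability at Dated Occupations via Change/Variability Decomposition
Version: 0.1.0
Authors@R: person("paleocvd", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for quantifying climate seasonality and predictability at
    dated archaeological occupations. Implements bioclimatic variable
    derivation from monthly climatologies (bio01, bio04, bio12, bio15),
    space-time extraction of climate series from gridded time-cubes with
    neighbourhood buffering and nearest-land relocation, a singular spectrum
    analysis based change/variability decomposition (CVD) whose variability
    percentage serves as an unpredictability proxy, nonparametric regional
    comparison statistics with dating-uncertainty sensitivity permutations
    and space-time background resampling, and a synthetic-data generator
    producing climate cubes and occupation inventories with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
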