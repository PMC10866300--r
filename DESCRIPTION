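Package: emitra
Title: Read-Across Estimation of Chemical Process Emissions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates environmental emissions of a chemical manufacturing
    process from measured emissions of structurally analogous processes by
    quantitative read-across. Identifies analogue source chemicals by
    fingerprint Tanimoto similarity, validates homologous chemical
    categories, fills physicochemical property gaps by within-category
    trend regression, checks process compatibility (catalyst class,
    conditions, pollution controls), maps species between processes by
    role and structural similarity, applies four estimation modes
    (closest analogue, category trend, average, conservative) with
    property-ratio read-across factors, and grades each estimate's
    uncertainty as low, moderate or high with full provenance. Ships the
    cumene to p-cymene alkylation case study as an embedded fixture and a
    generator of synthetic homologous series with known property and
    emission trends.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
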