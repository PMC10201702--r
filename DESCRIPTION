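Package: logtclub
Title: Log-t Convergence Testing and Club Clustering for Health Workforce Density Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tests the hypothesis of cross-country convergence in health workforce
    density (physicians, nurses and midwives per 10,000 population) with the
    Phillips-Sul time-varying factor model: relative transition paths, the trimmed
    log-t regression with Bartlett-kernel (Newey-West) robust inference, and the
    endogenous club-clustering algorithm (ordering, core-group search, membership
    sieving, recursion and club merging). Includes a seeded synthetic panel
    generator with known club structure for size, power and label-recovery
    studies, balanced-panel CSV input/output in long and wide layouts,
    Hodrick-Prescott trend smoothing, and the elasticity arithmetic used to relate
    physician density to income growth and to the Healthcare Access and Quality
    index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    lmtest,
    mclust,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
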