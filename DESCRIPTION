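Package: ccdesv
Title: Coupling Coordination Between Tourism Development and Ecosystem
    Service Value
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the coordinated development of a composite
    tourism-quality index and ecosystem service value (ESV) over a panel of
    cities and years. Implements equivalent-factor ESV valuation from
    land-use area tables, entropy-weight composite indexing of tourism
    indicators, the two-subsystem coupling coordination degree (CCD) model
    with its nine-type classification ladder, and panel regression of the
    CCD on its drivers (pooled, within/fixed-effects and Swamy-Arora
    random-effects estimators with the F, Breusch-Pagan LM and Hausman
    selection battery). A synthetic-data module generates city-year
    land-use compositions, indicator panels and driver panels with known
    ground truth so the full pipeline can be exercised and validated
    without external yearbook or land-cover data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
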