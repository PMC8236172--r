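Package: ehcvsim
Title: System Dynamics Simulation of the Hong Kong Elderly Health Care
    Voucher Scheme
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic stock-and-flow simulation of primary care
    utilization in an aging population under the Hong Kong Elderly Health
    Care Voucher (EHCV) scheme. An age-structured population model feeds
    weekly Euler-integrated visit flows that are split between the public
    and private sectors; voucher entitlements (amount schedule, age
    eligibility, carry-forward, chronic-condition add-on) generate
    private-sector voucher visits via a constant-budget-share demand with
    supplier-induced price inflation, scaled by a logistic
    willingness-to-join curve, and shifted between sectors through
    substitution fractions. Includes scenario comparison (amount
    escalation, age-eligibility lowering, designated chronic voucher),
    MAPE/R-squared calibration against annual claim expenditure, a
    synthetic fixture generator, and an anchored Hong Kong fixture
    reproducing published baseline and scenario trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
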