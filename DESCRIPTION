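Package: milkwt
Title: Plasma and Milk Pharmacokinetics and Milk Withdrawal-Time Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Non-compartmental pharmacokinetic analysis of intravenous
    concentration-time profiles in plasma and milk, milk-penetration metrics,
    exact small-sample Wilcoxon dose comparisons, and regression-based milk
    withdrawal-time estimation using a one-sided (95th percentile, 95%
    confidence) tolerance limit against a maximum residue limit. Includes a
    calibrated synthetic crossover-study generator with bi-exponential plasma
    disposition, Bateman-type milk curves, log-normal assay error and
    limit-of-quantification censoring, so every stage of the pipeline can be
    exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
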