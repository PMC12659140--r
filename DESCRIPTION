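Package: utilscan
Title: Tree-Based Scan Statistics for Healthcare Utilisation in Matched
    Registry Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis workflow for register-based studies of healthcare
    utilisation in matched child cohorts. Implements unconditional Bernoulli
    tree-based scan statistics over ICD-10 and ATC classification
    hierarchies with Monte-Carlo multiplicity adjustment, Kaplan-Meier-type
    inverse-probability-of-sampling weights and weighted 1:k matching on
    maternal age, person-time rates with exact conditional confidence
    intervals, nonparametric mean cumulative counts of recurrent events
    under death as a competing risk, and simulation-based power estimation
    for the scan design. A synthetic registry generator emulates cohort,
    event, and censoring structure so the full pipeline runs without access
    to confidential register data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
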