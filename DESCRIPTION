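Package: spectrascreen
Title: Control-Free Outlier Scoring of CRISPR Repair-Outcome Mutational Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of gene perturbation screens with mutational-spectra
    readout at CRISPR-induced double-strand break sites. Scores every gene for
    its effect on the distribution of repair outcomes without nontargeting
    controls, by treating spectra as compositions (isometric log-ratio
    transform), estimating a robust center and covariance with the minimum
    covariance determinant, and ranking genes by robust Mahalanobis distance
    unified across target sites. Selects "pseudo-control" genes approximating
    the wild-type spectrum, and provides the surrounding machinery: event
    categorisation into seven repair-outcome classes, per-replicate quality
    filters, geometric-mean spectrum aggregation, Jensen-Shannon distance,
    precision-recall ranking evaluation, hypergeometric enrichment with
    Benjamini-Hochberg correction, difference-matrix clustering, and a
    Dirichlet-multinomial screen simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
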