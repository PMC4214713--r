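Package: minedesign
Title: Maximally Informative Next Experiment Design for the Linear Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential Bayesian experimental design for the high-dimensional
    linear model (many more coefficients than observations). Maintains the
    exact conjugate Gaussian posterior ("ensemble") over regression
    coefficients, computes the Maximally Informative Next Experiment (MINE)
    criterion -- the determinant of the correlation matrix of predicted
    responses -- and constructs criterion-maximizing next-experiment batches
    by four eigenvector- and orthonormal-basis strategies. Includes the
    classical D-optimality (model refinement) criterion and its gradient,
    numerical verification of the MINE/D-optimality equivalence under the
    shared prediction-variance constraint, prior-scale selection, and a
    replicated simulation harness measuring discovery power and false
    positive rates under Benjamini-Hochberg multiple testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
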