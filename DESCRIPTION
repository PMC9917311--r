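Package: karyomie
Title: Deterministic Karyotype Evolution and Missegregation-Induced Extinction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A deterministic compartment-model framework for the evolution of
    cell populations structured by karyotype under chromosome missegregation.
    Builds sparse parent-to-daughter division tensors from the per-chromosome
    shift distribution, assembles the linear birth-death generator, and
    analyses missegregation-induced extinction (MIE): dominant-eigenvalue
    classification, Gershgorin-type sufficient conditions that rule MIE out,
    critical curves in the (missegregation rate, turnover rate) plane for
    homogeneous rates and for copy-number-dependent rate kernels, and a
    Kronecker factorization for joint viability constraints on many
    chromosomes. Also implements estimators of ploidy, turnover and
    missegregation rates from chromosome-level tumor/normal expression
    summaries and linear pathway-score calibrations, together with seeded
    synthetic-data generators for all of their inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
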