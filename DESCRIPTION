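Package: epistable
Title: Penetrance Tables for High-Order Epistasis Models
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calculates numeric penetrance tables from symbolic epistasis
    models of arbitrary interaction order. Given a model mapping multi-locus
    genotypes to penetrance expressions in a baseline parameter x and an
    effect parameter y, per-locus minor allele frequencies and one fixed
    target parameter (prevalence or heritability), the package solves the
    constrained nonlinear system that pins the maximum penetrance to 1,
    thereby maximizing the free parameter, verifies the solution against an
    order-dependent tolerable-error heuristic, and serializes the resulting
    table to CSV or to the model-file format of the GAMETES data simulator.
    Generalized threshold, additive and multiplicative model families are
    bundled, together with an independent bisection oracle for verification
    and a command-line interface for batch use.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Collate:
    'AllGenerics.R'
    'genotypes.R'
    'model.R'
    'solver.R'
    'oracle.R'
    'table.R'
    'cli.R'
RoxygenNote: 7.3.3
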