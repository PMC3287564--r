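Package: poisdeg
Title: Two-Sample Poisson Tests for RNA-Seq Differential Expression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares two Poisson means per gene to call differentially
    expressed genes from RNA-seq read counts with technical replicates.
    Implements six tests on summed lane counts (likelihood ratio,
    conditional binomial exact, Wald, Wald on log fold change,
    variance-stabilizing square-root transformation, and Fisher exact on
    the 2x2 read-count table), a seeded Monte-Carlo engine estimating
    their size and power over grids of Poisson means and replicate
    designs, and a gene-wise screening pipeline for count matrices with
    expression filters, fold-change reporting and DEG counting at
    multiple p-value cutoffs. A synthetic count-matrix generator
    emulating lane-level Poisson sampling is included, along with a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
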