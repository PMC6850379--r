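Package: fastz
Title: Fast-Z Molecular Evolution from Polymorphism, Divergence and
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing fast-Z (fast-X) evolution from codon
    alignments and expression data in female-heterogametic systems.
    Computes per-gene synonymous and nonsynonymous polymorphism,
    divergence and diversity by Nei-Gojobori counting; classifies genes
    as female-, male- or unbiased from RPKM ratios and as ovary- or
    gut-biased from a differential-expression table; estimates the
    proportion of adaptive nonsynonymous substitutions by the classic
    McDonald-Kreitman contrast and by fitting a gamma distribution of
    deleterious fitness effects to site frequency spectra under the
    Poisson random field model, yielding alpha, omega_a and omega_na;
    provides gene-resampling bootstrap confidence intervals, Z-to-autosome
    diversity ratios, a multiple regression of functional diversity on
    expression level, and an exact-model synthetic-data generator with
    recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    pracma,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
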