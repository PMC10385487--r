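Package: hybridgp
Title: Two-Stage Genomic Prediction of Combining Abilities in Hybrid Potato
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction of hybrid performance in diploid
    hybrid potato breeding programmes. Implements a two-stage analysis of
    multi-environment field trials: per-trial spatial mixed models with
    first-order autoregressive (AR1 and AR1xAR1) residual structures and a
    nugget effect, selected by AIC, producing weighted hybrid BLUEs; and
    second-stage genomic BLUP models for general and specific combining
    ability (GCA and GCA+SCA) with VanRaden additive and Vitezica dominance
    relationship matrices, genotype-by-trial kernels, and known-diagonal
    residual weighting. Includes marker quality control (minor allele
    frequency, missingness, polymorphism information content,
    kinship-corrected LD pruning), principal component analysis of markers,
    a restricted maximum likelihood (REML) engine for the required
    covariance structures, an evaluated-parent cross-validation scheme
    (0EP/1EP), and a synthetic hybrid-breeding data generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    yaml,
    optparse
Config/testthat/edition: 3
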