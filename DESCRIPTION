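Package: tindex
Title: Transcriptomic Index: A Continuous Sex Axis for Tumor Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Places each tumor transcriptome on a continuous female-to-male
    axis. The Transcriptomic Index (TI) of a sample is the Bayesian posterior
    probability that the sample is male given the recorded sexes of its
    nearest transcriptome neighbors, computed under a changepoint partition
    prior over the distance-ordered neighbor sequence with Beta-Bernoulli
    blocks (Bayesian nearest neighbors). Includes cohort-level leave-one-out
    TI estimation with optional sex-balanced observation weights, per-gene
    TI association with skew calling, one-sided Fisher gene-set enrichment of
    skewed genes against GMT collections, midrange-versus-pole expression
    contrasts, cohort summaries with incidence-rate-ratio regression, a
    synthetic cohort generator with planted sex-skewed gene modules for
    parameter-recovery testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
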