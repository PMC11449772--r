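Package: ironaccord
Title: Liver Iron Grading Accuracy from Multi-Echo T2* Relaxometry
Version: 0.1.0
Authors@R: person("Iron", "Accord", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to assess how reliably T2*-based liver iron estimates
    reproduce a reference iron-burden grade. Simulates multi-echo gradient
    echo magnitude signals with Rician noise for a synthetic patient cohort,
    fits the mono-exponential decay model with the long-echo truncation
    method, converts T2* to liver iron concentration with the Garbowski
    calibration, assigns the five-level iron-burden grade, and compares
    estimated against reference grades with crude and directly standardized
    diagnostic accordance rates across goodness-of-fit, echo-count and
    iron-burden strata, together with the accompanying nonparametric test
    battery (paired Wilcoxon, Kruskal-Wallis with Bonferroni correction,
    Spearman correlation, intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
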