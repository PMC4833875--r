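Package: rorscreen
Title: Disproportionality Screening of Adverse-Event Reports by Reporting Odds Ratio
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pharmacovigilance-style drug-repositioning screen over
    spontaneous adverse-event reports. Counts drug/reaction co-occurrence
    across report corpora (canonical JSONL or openFDA-style JSON), scores
    each drug by the reporting odds ratio (ROR) with a log-space two-sided
    Fisher exact test that remains informative far below double-precision
    underflow, ranks drugs by significance, and evaluates how well the
    ranking recovers a known-indication label set (ROC AUC, partial AUC,
    DCG/NDCG, threshold enrichment with conditional-MLE odds ratio).
    Includes a seeded synthetic-corpus generator with known ground-truth
    association strength for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
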