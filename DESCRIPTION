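Package: visiontriage
Title: Dynamic Bayesian Differential Diagnosis and Triage for Acute Vision Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential Bayesian differential diagnosis for acute vision loss.
    Implements belief updating over Yes/No/Don't-know clinical questions under a
    conditional-independence likelihood model, greedy question selection by
    expected pre-test to post-test probability shift, a ratio-based stopping
    rule, ranked differentials with anatomical cluster and urgency triage, and
    the diagnostic-accuracy machinery (top-k accuracy, per-cluster accuracy,
    urgency sensitivity and specificity with exact Clopper-Pearson confidence
    intervals) needed to evaluate such an engine against gold-standard
    diagnoses. Ships an illustrative knowledge base, a reconstructed canonical
    study cohort, and a synthetic questionnaire cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
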