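Package: sliceleak
Title: Subject-Identity Leakage in Slice-Level Hold-Out Evaluation of fMRI Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An experiment harness demonstrating how slice-level train/test
    splitting of 4D BOLD fMRI data leaks subject identity into the test set
    and inflates classifier performance relative to subject-level splitting.
    Provides a synthetic multi-subject fMRI cohort generator with controllable
    subject-fingerprint and diagnostic-effect strength, depth-by-time slice
    extraction with percentile-based mean-signal filtering, the two contrasted
    hold-out strategies with a leakage audit, a compact seeded CNN classifier,
    and accuracy/sensitivity/specificity reporting with median aggregation and
    a per-problem leakage-gap summary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
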