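Package: dermshift
Title: Diagnosing and Closing Condition-Distribution Shift for Multiclass Diagnostic Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic-data machinery for studying how condition-distribution
    shift between a development dataset and a new clinical setting degrades a
    multiclass diagnostic classifier, and for closing that gap. Provides a
    generator for teledermatology-style cases (condition taxonomy, image
    embeddings, structured metadata, simulated dermatologist rater panels),
    inverse-rank fusion of rater differentials into a ranked reference
    standard, a metadata-fused (FiLM) classifier head trained with focal loss,
    top-3 and variable-size prediction-set evaluation with sensitivity-targeted
    threshold calibration, one-vs-rest temperature recalibration over condition
    categories, Metropolis-Hastings resampling of the development set toward a
    target category distribution, condition-aware augmentation with rarer
    conditions, inverse-probability-weighted accuracy metrics with bootstrap
    confidence intervals, error-factor regression analyses, and an experiment
    grid comparing adaptation strategies on a frozen evaluation split.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse,
    withr
Config/testthat/edition: 3
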