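Package: rankstab
Title: Ranked Network-Feature Stability for Dynamic Functional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs sliding-window Pearson-correlation networks from
    multichannel physiological time series (e.g. resting-state EEG) and
    quantifies the temporal persistence of ranked network features -- the
    strongest link, top-m link sets, the most central node and the node of
    highest weighted clustering -- against a binomial null model of
    independent networks.  Scans window lengths to locate the timescale at
    which each feature is most stable, aggregates stability across subjects
    (group means, jackknife envelopes, pooled intra-group stability,
    upsampling splits), relates the resulting six stability metrics to
    demographic and cognitive covariates, and uses them in a random-forest
    group-classification protocol with reference baselines.  Includes a
    synthetic-data generator with planted persistent couplings so the whole
    pipeline is testable against known ground truth, readers for European
    Data Format (EDF) and delimited recordings, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
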