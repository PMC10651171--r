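Package: herclust
Title: Heartbeat-Evoked Response Analysis Under the Local-Global Auditory Paradigm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse heartbeat-evoked responses (HERs) and auditory
    event-related potentials (ERPs) recorded under the local-global auditory
    oddball paradigm, as used in the study of disorders of consciousness.
    Provides a synthetic-cohort generator (EEG with a cardiac field artifact,
    RR-variable heartbeats, and planted stimulus- and heartbeat-locked group
    effects), the standard preprocessing chain (Butterworth band-pass,
    iterative noisy-channel rejection, ICA-based ECG recovery, spherical-spline
    interpolation, common-average referencing), R-peak detection with ectopic
    flagging, stimulus- and heartbeat-locked epoching with explicit rejection
    rules, non-parametric spatiotemporal cluster-permutation tests based on
    unpaired Wilcoxon Z maps with a max-statistic Monte Carlo correction, a
    surrogate-heartbeat specificity control, rank-based cohort statistics with
    Bonferroni control, and cross-validated linear discriminant classification
    of combined clustered effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'utils.R'
    'cardiac.R'
    'classify.R'
    'cluster.R'
    'io.R'
    'epochs-io.R'
    'epochs.R'
    'fastmaps.R'
    'neighbors.R'
    'stats.R'
    'surrogate.R'
    'preprocess.R'
    'simulate.R'
    'pipeline.R'
    'studies.R'
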