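Package: mammoqc
Title: Phantom-Based Image Quality and Dose Analysis for Digital Mammography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Task-based quality-control analysis of "for processing" digital
    mammography images acquired on a PMMA phantom carrying copper and
    aluminium inserts. Implements the signal-difference-to-noise ratio,
    presampled slanted-edge modulation transfer function, normalized noise
    power spectrum, the non-pre-whitening-with-eye-filter (NPWE) model
    observer detectability index for small disc tasks, and average glandular
    dose per the European reference (EUREF) formalism. A deterministic
    acquisition simulator of an amorphous-selenium detector with a movable
    seven-position automatic exposure control (AEC) sensor drives
    reproducible comparison studies of reference, misused and manual
    exposure techniques, summarized with Kruskal-Wallis and
    Bonferroni-corrected Dunn statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'specs.R'
    'metrics.R'
    'clinical.R'
    'dose.R'
    'stats.R'
    'npwe.R'
    'nps.R'
    'mtf.R'
    'simulate.R'
    'experiments.R'
    'io.R'
    'mammoqc-package.R'
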