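Package: methyldyn
Title: Longitudinal Dynamics of Smoking-Associated DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-time-point analysis pipeline for smoking-associated DNA
    methylation on Illumina 450K-style arrays: detection and bead-count
    filtering, quantile normalization, beta to M-value transformation,
    control-probe principal-component technical adjustment, a cross-sectional
    epigenome-wide association gate, per-site random-intercept linear mixed
    models (restricted maximum likelihood with Satterthwaite degrees of
    freedom) relating smoking-category by time interactions to methylation
    change, and fine-scale reversion statistics (binned median changes,
    dynamism interquartile ranges, direction-consistency proportions and
    cross-sectional versus longitudinal coefficient correlations). Includes a
    seeded synthetic two-visit cohort generator emulating current, former and
    never smokers with exponential post-cessation decay of smoking effects,
    so the whole pipeline is testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    ggplot2,
    withr
Config/testthat/edition: 3
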