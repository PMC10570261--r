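Package: cardiact
Title: Quantification of Dual-Tracer Constant-Infusion Cardiac PET/MRI Studies
Version: 0.1.0
Authors@R:
    person("Lawson", "Imaging Tools", email = "imaging-tools@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for simultaneous constant-infusion FDG-PET and
    gadolinium MRI of the infarcted heart with mid-infusion glucose
    suppression.  Provides Patlak graphical analysis of tissue/plasma
    time-activity curves restricted to protocol windows and the derived
    metabolic rate of glucose, extracellular volume (ECV) from native and
    post-contrast T1 of myocardium and blood, Renyi-entropy thresholding and
    integrated density for punctate immunofluorescence, percent-fibrosis
    quantification of trichrome slides, a tissue-fraction ledger bounding the
    viable-myocyte volume in infarcted tissue, the accompanying statistical
    comparisons (paired t, Bonferroni, exact Mann-Whitney, Pearson), and a
    seeded synthetic-data generator so the whole pipeline is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
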