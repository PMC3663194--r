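Package: hemoqc
Title: Hemolysis Quality Control for Cell-Free microRNA RT-qPCR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality control of circulating cell-free microRNA measurements
    against red-blood-cell contamination. Scores hemolysis from plasma
    absorbance spectra (A414 Soret band, 541/576 nm Q-bands), computes
    un-normalized 2^-deltaCq fold changes between matched hemolyzed and
    non-hemolyzed plasma pairs, filters microRNAs by detectability, tiers
    them by hemolysis susceptibility, analyzes Cq trajectories across RBC
    spike dilution series, and selects candidate biomarker and endogenous
    control subsets. Includes a synthetic-data generator built on a linear
    RBC-contamination mixing model so every pipeline stage can be exercised
    and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
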