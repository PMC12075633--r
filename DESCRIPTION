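Package: fretdyn
Title: Single-Molecule FRET Analysis of Transporter Association-Dissociation Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule FRET experiments that
    monitor ATP-driven association and dissociation of the substrate-binding
    subunit (S-component) of an energy-coupling factor (ECF) transporter
    reconstituted in liposomes. Provides a forward simulator of two-state
    Markov switching with ALEX frame layout and camera photophysics, spot
    extraction from dual-view image stacks, the trace-correction chain
    (median prefilter, background subtraction, crosstalk and direct-excitation
    correction, Chung-Kennedy edge-preserving filtering), an anticorrelation
    based dynamic/static classifier, FRET-efficiency histograms and
    two-population peak ratios, change-point based dwell-time extraction with
    censoring-aware exponential fits, time-to-first-event survival analysis,
    hyperbolic EC50 dose-response fits, summary-statistics Welch ANOVA with
    Games-Howell/Tukey pairwise tests, confocal PIE/ALEX burst analysis, and
    small deterministic helpers (Forster relation, C-alpha distances from PDB
    files, Gompertz growth-lag fits, coupled-assay ATPase turnover).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    bio3d,
    tiff
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
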