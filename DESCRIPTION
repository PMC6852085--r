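Package: rvpac
Title: Single-Beat Right Ventricular-Pulmonary Arterial Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for haemodynamic analysis of right ventricular (RV)
    function and RV-pulmonary artery coupling from pressure and flow
    waveforms. Implements the single-beat method: segmentation of RV
    pressure into beats, location of the isovolumic contraction and
    relaxation phases from dP/dt landmarks, sine-wave extrapolation of the
    maximal isovolumic pressure (Pmax), and per-beat end-systolic elastance
    (Ees), arterial elastance (Ea) and their ratio, summarized as the
    median over at least ten consecutive beats. Also provides body-weight
    indexed haemodynamic indices, gravimetric and histological ratio
    metrics, embolization protocol arithmetic, relative gene-expression
    quantification by the delta-delta-Ct method with a multi-reference
    panel, permutation-based group and interaction statistics, and a
    seeded time-varying-elastance/windkessel simulator that generates
    ground-truthed synthetic recordings and qPCR tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
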