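Package: aggimmuno
Title: Mechanistic Models of Aggregate-Driven Immunogenicity of Therapeutic Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulators for two mechanisms by which aggregates of therapeutic
    protein products may drive anti-drug-antibody (ADA) responses. A
    deterministic mass-action model of sequential multivalent aggregate
    binding to B-cell receptors quantifies formation of signal-transducing
    complexes (aggregates cross-linking at least s receptors), with an exact
    Gillespie stochastic oracle for validation at small copy numbers. A
    minimal multiscale T-cell-dependent model (two-compartment
    pharmacokinetics, endosomal antigen processing, competitive MHC class II
    peptide loading, danger-signal-driven dendritic-cell maturation, and a
    17-subgroup affinity-maturation ladder of B cells) reproduces the
    directional effects of internalization and degradation rates, epitope
    number and affinity, and danger signal on cumulative ADA production.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
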