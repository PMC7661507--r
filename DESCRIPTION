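Package: polyion
Title: Kinetics and Equilibria of High-Affinity Polyelectrolyte Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-state kinetic and equilibrium analysis of high-affinity
    complexes between oppositely charged intrinsically disordered proteins,
    exemplified by the prothymosin-alpha/linker-histone-H1 system. Implements
    coupled binding equilibria with transient ternary complexes (PPH, PHH),
    two/three/four-state kinetic generators and their aggregate dwell times,
    photon-by-photon maximum-likelihood estimation of binding kinetics from
    single-molecule FRET time traces, burst selection and recurrence analysis
    of single particles, stopped-flow and FCS/PFG-NMR observable fits,
    Bloch-McConnell NMR lineshape reconstruction, and potential-of-mean-force
    post-processing (1-D WHAM, equilibrium constants, and diffusion-limited
    association rates with capture-radius detection). A synthetic-data module
    generates every input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
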