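Package: circlock
Title: Simulation and Bifurcation Analysis of Protein-Sequestration
    Circadian Clock Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing a family of dimensionless
    models of the mammalian circadian clock built on stoichiometric
    sequestration of the BMAL1:CLOCK activator by the PER:CRY repressor.
    Supports variable negative-feedback loop length, linear or
    Michaelis-Menten nuclear PER degradation, two transcription rate laws,
    and auxiliary REV-ERB (negative) and ROR (positive) feedback loops on
    Bmal1 expression. Provides closed-form and numerical Hopf-bifurcation
    loci, two-parameter oscillatory-domain scans with period maps, a
    five-point robustness criterion, calibration of the PER:BMAL1
    dissociation constant from oscillation amplitude, phase-dispersed
    population averaging, a baseline Goodwin oscillator with the secant
    condition, and constrained simulated-annealing parameter searches.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
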