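Package: mirburden
Title: Resource-Aware Modelling of miRNA-Mediated Gene Expression Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Deterministic resource-aware models of microRNA-mediated
    transgene downregulation in mammalian cells. Implements a
    ribosome-competition model with closed-form steady states and resource
    demand coefficients, a finite-RNase degradation model exhibiting a
    queueing effect on non-target transcript decay, stiff ODE simulation
    (steady state, miRNA binding-constant sweeps, transcription-halt decay
    experiments), biphasic decay-phase detection, and regularised
    differential-evolution fitting of model parameters to five-condition
    reporter fold-change data, with a synthetic-data generator for
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
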