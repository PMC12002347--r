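Package: exp2plateau
Title: Plateau Potentials in Pharyngeal Muscle with Ultrafast Potassium
    Inactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley style) simulation of the
    Caenorhabditis elegans pharyngeal corpus muscle, centred on a potassium
    current with ultrafast (or finite time-constant) voltage-dependent
    inactivation modelled on the EXP-2 channel. Provides the membrane model
    with T-type and L-type calcium currents, deterministic excitatory and
    inhibitory synaptic event schedules, Poisson shot noise on the inhibitory
    synaptic conductance, event-aware stiff integration via deSolve, plateau
    detection and regime classification of voltage traces, and rank-based
    (Mann-Whitney) comparison of plateau-duration samples with an effect-size
    summary. Includes drivers for conductance-space sweeps, noise-robustness
    experiments over the inactivation midpoint, and inactivation/synaptic
    timescale interaction studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
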