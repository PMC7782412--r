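Package: SpikeForge
Title: Ground-Truth Extracellular Recording Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A fast, controllable testbench simulator for extracellular
    spiking activity on multi-electrode arrays. Simulation is split in two
    phases: generation of a library of extracellular action potential
    templates (parametric cortical cell models, line-source forward model on
    configurable probe geometries, optionally with drifting trajectories),
    and synthesis of recordings (stochastic spike trains, rule-based
    template selection, bursting-modulated convolution, spatio-temporal
    synchrony control, drift playback, four additive noise models, optional
    filtering). All randomness is seed-controlled and outputs are
    self-describing HDF5 containers carrying full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    signal,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
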