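Package: loihisim
Title: Fixed-Point Emulation of the Loihi Neuromorphic Computational Unit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A software emulator for the computational unit of the Loihi
    neuromorphic chip: integer leaky integrate-and-fire dynamics obtained by
    forward-Euler discretization with round-away-from-zero arithmetic, the
    mantissa/exponent synaptic-weight codec with sign modes and 21-bit
    clipping, pre- and post-synaptic eligibility traces with stochastic
    rounding, a restricted learning-rule expression language with epoch-gated
    plastic weight updates, and a discrete-time network scheduler with spike
    generators and state/spike monitors. Includes a YAML configuration
    schema, fixture networks (single neuron, chaotic recurrent network,
    single-plastic-synapse STDP), CSV recording output and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
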