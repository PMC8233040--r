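Package: hdspeed
Title: Angular Head Speed Coding from Head-Direction Input via Depressing Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a thalamo-retrosplenial circuit in which an ensemble of
    head-direction (HD) cells drives a postsynaptic low-rheobase (LR) readout
    through short-term-depressing Tsodyks-Markram synapses, and quantifies how
    the postsynaptic firing rate encodes angular head speed and head direction.
    Provides synthetic head-direction trajectory generation (Ornstein-Uhlenbeck
    angular velocity emulating 40 Hz tracking), Gaussian HD tuning curves with
    Beta-distributed parameters and anticipatory firing, inhomogeneous Poisson
    spike generation with refractoriness, event-driven Tsodyks-Markram synapse
    dynamics with exhaustive-grid parameter fitting, rate-based and
    Hodgkin-Huxley point-neuron readouts, lagged correlation and mutual
    information coding analysis, circular Wasserstein heterogeneity scores,
    and a mean-field reduction of the circuit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
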