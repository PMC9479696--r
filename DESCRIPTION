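Package: snnet
Title: Surrogate-Gradient Training of Adaptive Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spiking neural networks of adaptive leaky integrate-and-fire
    (adLIF) neurons for sequence classification, trained by backpropagation
    through time with surrogate gradients (boxcar pseudo-derivative by
    default). Implements the normalized discrete-time LIF/adLIF dynamics with
    trainable heterogeneous neuron parameters, recurrent layers with
    zero-diagonal feedback, four readout schemes, non-spiking baselines (MLP,
    RNN, light-gated and gated recurrent units), event-based dataset reading
    and time binning, log-mel filterbank features, Poisson rate encoding,
    synthetic spatiotemporal spike tasks, random connection sparsification,
    and synaptic-operation (AC/MAC) energy accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
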