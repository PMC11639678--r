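Package: csdp
Title: Contrastive Signal-Dependent Plasticity for Recurrent Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates recurrent circuits of leaky integrate-and-fire (LIF)
    neuron layers that run fully in parallel and learn with contrastive
    signal-dependent plasticity (CSDP): a local, self-supervised rule whose
    per-neuron modulator is the derivative of a layer-wise logistic
    "goodness" loss over filtered spike traces. Includes Bernoulli spike
    encoding of images (IDX readers/writers and a synthetic glyph data
    generator), on-the-fly negative-sample synthesis for supervised and
    unsupervised training, a local spiking generative head for pattern
    reconstruction, a fast spiking classifier head with a goodness-scan
    alternative, and an Adam-based trainer with hard synaptic range
    constraints.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
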