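Package: spikelat
Title: Spiking Autoencoders with Temporal Coding and Exact Spike-Time Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Event-based simulation and training of feedforward spiking
    neural networks that communicate by single spike times (latency coding).
    Membrane potentials follow alpha-function synaptic kernels, output spike
    times have a closed form via the principal branch of the Lambert W
    function, and networks are trained by backpropagation with exact
    spike-time derivatives. Includes latency-targeted autoencoder training
    with learnable synchronisation pulses, analog image encoding with
    brightness inversion, a clipped-Gaussian noise model for denoising
    experiments, IDX image file input/output, a deterministic synthetic
    image generator for desk-scale experiments, and diagnostic summaries of
    spike-time and weight distributions.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
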