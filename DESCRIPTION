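Package: tomsnn
Title: Theory-of-Mind Spiking Neural Networks in Multi-Agent Gridworlds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and training of a modular theory-of-mind (ToM) spiking
    neural network in a partially observable 7x7 gridworld. Provides leaky
    integrate-and-fire neuron dynamics with population coding and winner-take-all
    decoding, spike-timing-dependent plasticity (STDP) with eligibility traces
    and reward modulation (R-STDP), a multi-agent gridworld with line-of-sight
    occlusion and style-specific reward functions (reckless, experienced,
    cautious), four ToM submodules (perspective taking, policy inference,
    action prediction, state evaluation), and the with/without-ToM safety
    evaluation protocol with performance scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
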