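Package: dawave
Title: Dopamine-Modulated Spiking Networks with Traveling-Wave Timing Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulator for a dual-pathway dopaminergic spiking
    neural network that learns tactile preferences by classical conditioning.
    Implements Izhikevich neurons with four-receptor conductance synapses and
    axonal delays, excitatory and Mexican-hat inhibitory STDP,
    eligibility-trace dopamine-modulated STDP with per-group dopamine pools,
    and dopamine-gated post-synaptic facilitation. Includes a synthetic
    trackball hand-sweep generator matched to measured sweep statistics,
    builders for the prefrontal/striatal (decremental) and thalamic/insular
    (incremental) pathways, experiment protocols for traveling-wave
    development, conditioning and extinction, and metrics for dopamine
    burst/dip detection, wave scoring and synaptic weight maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
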