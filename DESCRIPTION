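Package: ecbstdp
Title: Biophysical Model of Endocannabinoid- and NMDAR-Mediated Corticostriatal STDP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates spike-timing dependent plasticity (STDP) at the
    corticostriatal synapse with a biophysically detailed signaling model of
    the postsynaptic medium-sized spiny neuron. Two coupled pathways set the
    synaptic weight: an NMDAR to calmodulin/CaMKII pathway whose bistable
    switch drives the postsynaptic weight, and an mGluR/calcium to
    endocannabinoid (2-AG, anandamide) to presynaptic CB1R pathway whose
    activation level drives the presynaptic weight through a three-threshold
    plasticity rule. The package integrates the full stiff ODE system over
    paired pre/postsynaptic stimulation protocols, computes plasticity maps
    over spike timing, number of pairings and pairing frequency, emulates
    receptor knockouts and enzyme inhibition, and ranks parameter sensitivity
    with Monte-Carlo standardized regression coefficients.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
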