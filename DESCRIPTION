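Package: hplast
Title: Synaptic and HCN Channel Plasticity Coupling in Compartmental CA1 Neuron Models
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.org>
Description: Conductance-based multicompartment simulation of a hippocampal CA1
    pyramidal neuron with distance-dependent passive properties and voltage-gated
    channel gradients, Goldman-Hodgkin-Katz AMPA/NMDA synapses, calcium-dependent
    synaptic weight dynamics, and a linear coupling between total synaptic weight
    change and somatic HCN conductance. Includes stimulus generators (Poisson and
    theta-modulated trains, asymmetric ramp currents), a measurement battery
    (EPSP amplitude, dendritic democracy tuning, input resistance, input/output
    response profiles, RMSE), rate-coding mutual information analysis, and the
    protocol suite for firing-rate homeostasis and place-field stability studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), deSolve, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
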