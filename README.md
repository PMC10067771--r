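# hplast

Conductance-based simulation of firing-rate homeostasis through coupled
synaptic and HCN-channel plasticity in a hippocampal CA1 pyramidal neuron
model.

## The problem

Hebbian plasticity is a positive feedback loop: stronger synapses drive more
spiking, more spiking drives more calcium, more calcium drives stronger
synapses. In a real neuron the loop does not run away — it shuts the cell
down, because sustained depolarization inactivates sodium channels
(depolarization-induced block) and the input/output (I/O) relationship
collapses. `hplast` implements and tests a homeostatic counter-mechanism: a
linear coupling between the change in total synaptic weight and the somatic
HCN (h) channel conductance,

    g_h(t + dt) = g_h(t) * (1 + dW * slope),
    dW = (sum_i w_i(t + dt) - sum_i w_i(t)) / sum_i w_i(t),

applied every 100 ms during plasticity induction and rescaling the whole
somato-apical HCN gradient. HCN conductance shunts the membrane and lowers
input resistance, so growing it alongside the synapses counteracts the
runaway loop. The package is for computational neuroscientists who want to
study this rule quantitatively: when it restores the I/O profile, how the
optimal slope depends on baseline synaptic strength and HCN levels, what it
costs in rate-coded mutual information, and whether it stabilizes
place-field activity under theta-modulated drive.

The model underneath is a multicompartment CA1 pyramidal cell:
distance-dependent passive gradients and d-lambda discretization, Na/KDR/KA/
CaT/HCN conductances with somato-apical gradients, GHK-based AMPA/NMDA
synapses with magnesium block, a submembrane calcium shell per synapse, and
the calcium-control weight rule `dw/dt = (Omega(Ca) - w)/tau(Ca)`. The
integrator is compiled (Rcpp): implicit branched-cable solve at a fixed
25 microsecond step. See `vignettes/hplast-methods.Rmd` for the full model
account and design rationale.

## Worked example

Build the reduced desk-scale study (synthetic morphology, 21
democratically tuned synapses), measure the baseline I/O profile, then sweep
the coupling slope to find the homeostatic optimum:

```r
library(hplast)

omega(c(0, 0.45, 1))        # weight targets at rest / LTD trough / LTP
#> 0.25 0.0004191877 1
learning_tau(c(0, 0.55))    # seconds; ~3 h at rest, ~1.6 s at threshold
#> 10001 1.601016

pre <- reduced_preset()
model <- build_study(pre)
model
#> neuron model: 51 compartments, 21 synapses, gh_scale = 1

base <- io_profile(model, pre$freqs, pre$trials, seed = 11)
round(rowMeans(base$rf), 1)
#> 11.3 19.3 28.7 35.0 42.0 51.0 57.3 60.3 67.7 74.7   # Hz at 2..20 Hz drive

stimuli <- assign_induction_stimuli(model, pre$induction_s, seed = 7)
sweep <- optimize_slope(model, stimuli, "rmse_min", preset = pre,
                        seed = 11, base_profile = base)
rbind(slope = sweep$slopes, rmse = round(sweep$objective, 2))
#> slope  0.00  2.50 5.00 7.50 10.0 12.50 15.00 17.50 20.00
#> rmse  13.39 13.04 3.21 2.42  1.6  1.68  3.17  4.39  5.89
sweep$optimal_slope
#> 10

profile_information(base)
#> mutual information: 2.7061 bits (H = 5.6736, H_noise = 2.9675)
```

Reading the numbers: at slope 0 (synaptic plasticity alone) the induced LTP
left-shifts the I/O profile and the RMSE against baseline is 13.4 Hz; at the
optimal slope the evolved HCN conductance restores the profile to within
1.6 Hz of baseline; past the optimum the shunt overcompensates and the RMSE
curve turns back up — the inverted-bell signature of the homeostatic rule.
`iterate(model, 7, stimuli, coupling = "optimal", ...)` chains induction,
permeability updates and profiles across repeated stimulation (with the
optimal slope re-estimated and decreasing each iteration), and
`build_place_study()` / `place_field_study()` run the theta-driven
place-field variant.

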