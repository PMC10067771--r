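---
title: "Coupled synaptic and HCN conductance plasticity in a compartmental CA1 model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled synaptic and HCN conductance plasticity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Hebbian synaptic plasticity is intrinsically unstable: potentiation
increases synaptic drive, which increases postsynaptic activity, which
drives further potentiation. In a spiking neuron this positive feedback does
not diverge — it collapses, because sustained depolarization inactivates
sodium channels and the cell stops firing altogether (depolarization-induced
block). A cell that has lost its input/output (I/O) relationship transmits no
information, however strong its synapses are.

`hplast` implements a biophysical account of how a hippocampal CA1 pyramidal
neuron can escape this trap: a homeostatic rule that ties the somatic
conductance of HCN (h) channels linearly to the ongoing change in total
synaptic weight. HCN conductance lowers input resistance and dampens
temporal summation, so scaling it up as synapses strengthen counteracts the
runaway loop. The package provides the full simulation stack needed to study
this rule quantitatively — morphology, channel gradients, GHK synapses,
calcium-dependent weight dynamics, the coupling rule, the measurement
battery, and rate-coding information analysis — and a reduced desk-scale
preset on which every mechanism runs in minutes.

## Model components

### Morphology and passive structure

Morphologies are either read from SWC reconstructions (`load_swc()`) or
generated synthetically (`make_morphology()`): a cylindrical soma, a tapered
apical trunk whose terminal path distance from the soma is 425 um, oblique
side branches, basal dendrites and an axon. Specific membrane resistivity
and axial resistivity fall sigmoidally along the somato-apical axis

$$R_m(x) = R_{m,\max} + \frac{R_{m,\min} - R_{m,\max}}{1 + e^{(d - x)/k}}$$

with $R_{m,\max} = 125$, $R_{m,\min} = 85$ kOhm cm^2, $d = 300$ um,
$k = 50$ um (and 120 -> 70 Ohm cm for $R_a$); basal dendrites and the axon
take somatic values. The source model lists two values (50 um and 14 um) for
the axial-gradient slope constant; the package defaults to 50 um — the value
shared with the membrane-resistivity gradient — and exposes the choice in
`passive_params()`. Compartmentalization follows the d-lambda rule: each
section is split into the smallest odd number of equal compartments shorter
than $0.1\,\lambda_{100}$, with the AC length constant evaluated from local
diameter and the distance-dependent resistivities in two passes (section
midpoint first, compartment midpoints after).

### Channels

Five conductances are present: Na and delayed-rectifier K (uniform), A-type
K (linear apical gradient, proximal/distal kinetic variants switching at
100 um), HCN and T-type Ca (sigmoidal apical gradients). The HCN
half-activation voltage shifts from -82 mV (x <= 100 um) linearly to -90 mV
(x >= 300 um). The axon is passive except for a 30 um initial segment with
five-fold somatic Na density. All gating kinetics are *named closed forms
with coefficients* pinned in `inst/extdata/channels.yaml`, so the rate
functions are inspectable and unit-testable rather than hidden in compiled
mechanism files. The Na/KDR/KA rates follow the trap (linoid) and
Borg-Graham thermodynamic forms of the standard CA1 literature; T-type
gating uses the standard bell-shaped time constants; q10 factors adjust all
time constants to 34 degrees C.

Two coefficients were deliberately set for the reduced-scale model and
differ from common full-scale values (see *The reduced preset* below): the
KDR rate scale (`a0 = 0.1 /ms`, i.e. a faster delayed rectifier) and the
T-type inactivation half-voltage (-85 mV). The dendritic Na slow
inactivation gate is a simplified two-parameter gate (non-inactivating
fraction `ar2 = 0.4`, sigmoidal steady state at -58 mV, time constant
1.2 s at rest falling to ~0.2 s when depolarized); it is active in dendritic
compartments only.

### Synapses, calcium, and the weight rule

Each synapse co-localizes AMPA and NMDA receptors, both modeled as GHK
(constant-field) permeabilities rather than ohmic conductances: AMPA carries
Na and K (1:1), scaled by the synaptic weight $w$; NMDA carries Na, K, Ca
(1:1:10.6 relative permeability) gated by the magnesium block
$MgB(v) = [1 + (\mathrm{[Mg]_o}/3.57)\,e^{-0.062 v}]^{-1}$. Gating is the
normalized double exponential $s(t) = a(e^{-t/\tau_d} - e^{-t/\tau_r})$
(2/10 ms AMPA, 5/50 ms NMDA), superposed linearly over presynaptic events.
The NMDA:AMPA permeability ratio (NAR) is 1.5 and is restored after every
plasticity step.

NMDA and T-type calcium currents feed a 0.1-um submembrane shell,

$$\frac{d[\mathrm{Ca}]_i}{dt} = -\frac{10^4\, I_{Ca}}{3.6\, dpt\, F}
  + \frac{[\mathrm{Ca}]_\infty - [\mathrm{Ca}]_i}{\tau_{Ca}},$$

with $\tau_{Ca} = 30$ ms and $[\mathrm{Ca}]_\infty = 10^{-4}$ mM. The shell
constant 3.6 is implemented verbatim as printed in the source model; note
that the standard electro-diffusion factor would be $z F = 2F$, so the 3.6
(with the $10^4$ units factor) should be read as part of an empirical shell
coefficient, not re-derived.

The weight obeys the calcium-control rule
$dw/dt = (\Omega([\mathrm{Ca}]_i) - w)/\tau([\mathrm{Ca}]_i)$ with the
double-sigmoid target $\Omega$ (LTD trough between 0.35 and 0.55, LTP
plateau at 1) and learning time constant
$\tau = P_1 + P_2/(P_3 + [\mathrm{Ca}]_i^{P_4})$ — about 3 hours at resting
calcium, 1 s at high calcium. **Units of the calcium argument.** The shell
equation above produces concentrations in mM, and the package passes them to
$\Omega$ and $\tau$ in mM. On this scale the simulated synaptic transients
(~0.1–1.5 mM at the shell) straddle the 0.35/0.55 thresholds exactly as the
rule requires; interpreting the thresholds on the uM scale of the original
calcium-control literature would put every simulated transient three orders
of magnitude above both thresholds and reduce the rule to a binary LTP
switch.

### The HCN coupling rule

Every 100 ms of induction the somatic maximal HCN conductance is updated as

$$g_h \leftarrow g_h\,(1 + \Delta W \cdot \mathrm{slope}), \qquad
  \Delta W = \frac{\sum_i w_i(t{+}\Delta t) - \sum_i w_i(t)}{\sum_i w_i(t)},$$

and the whole spatial HCN gradient is rescaled through the somatic value
(plasticity of h channels is spatially widespread). $\Delta W$ is the
*fraction* of Eq-level weight change; a percent convention (100x slope
rescale) is available via `hcn_coupling(dw_percent = TRUE)`. Because the
update compounds geometrically across update intervals, a slope that is
optimal for one induction is too large after permeabilities have grown; the
iterated protocol therefore re-optimizes the slope before each iteration
(`iterate(coupling = "optimal")`), and the optimal slope falls monotonically
with iteration number.

### Engine

The integrator (Rcpp) advances the branched cable with backward Euler at a
fixed 25 us step: ohmic membrane and axial terms are implicit (Hines
elimination over the parent-ordered tree), gating variables and calcium
shells use exponential Euler against voltage lookup tables built from the
channel configuration, and GHK currents are linearized about the present
voltage so that their positive chord conductance enters the implicit matrix
(explicit GHK sources destabilize the step once permeabilities have grown by
plasticity). Spike detection is an upward crossing of -20 mV with a 2 ms
refractory period.

**Operating point.** All protocols run at a fixed holding potential (-65 mV
for Poisson protocols, -66 mV for theta protocols). The engine implements
this by balancing the leak reversal per compartment at initialization — a
distributed holding bias — so every condition starts at its stated operating
point and a changed HCN conductance acts through its shunt rather than
through a shift of the resting potential. Because gating variables are also
initialized at their steady states, the initial condition is the resting
state itself; protocol runs keep only a short 50 ms settle window (excluded
from all outputs) as a guard.

## Measurements and information

* `epsp_amplitude()` — single-event somatic peak minus baseline, AMPA only.
* `democracy_tune()` — multiplicative fixed-point iteration on per-synapse
  permeabilities until all somatic EPSPs match their targets (dendritic
  democracy); converged permeabilities grow with distance.
* `input_resistance()` — slope of the steady-state V–I line over current
  pulses (-50 to +50 pA in 10 pA steps).
* `io_profile()` — spike counts in 1 s windows with all synapses driven by
  independent Poisson trains at each stimulus frequency; trial substreams
  are deterministic functions of (seed, frequency, trial, synapse), so
  baseline and post-plasticity profiles face identical input patterns and
  `rmse()` (root mean squared difference over all frequency x trial cells)
  measures the profile shift, not trial noise.
* `conditional_distributions()` / `mutual_information()` — per-stimulus
  Gaussian response distributions (mean/SD over trials, renormalized on a
  1–100 Hz response grid, zero-SD rows collapse to the nearest bin), total
  response entropy $H$, noise entropy $H_{noise}$, and
  $I_m = H - H_{noise}$ under a uniform stimulus distribution.

## Protocols

`build_study()` constructs the tuned baseline; `assign_induction_stimuli()`
draws one stimulus frequency per synapse uniformly from 4–12 Hz and one
Poisson train per synapse, as a pure function of the seed so the same
spatio-temporal pattern is reused across conditions and iterations.
`induce_plasticity()` runs induction (AMPA+NMDA, weights evolving, coupling
optional); `apply_plasticity()` folds final weights into permeabilities
(`p_ampa * w_final / w_init`, weights reset, NAR restored — the only mapping
consistent with $w$ multiplying the AMPA permeability) and makes the evolved
HCN scale the new baseline. `iterate()` chains these; `optimize_slope()`
sweeps the coupling slope for RMSE minimization or MI maximization (ties
break toward the smaller slope; boundary optima trigger automatic upward
grid widening and are flagged if they persist); `sensitivity_sweep()`
re-optimizes along a synaptic-scale or baseline-HCN axis.

The place-field study (`build_place_study()`, `place_field_study()`) uses
theta-modulated inputs: events are drawn per 125 ms theta cycle with a
Poisson count (mean `A = 1` per synapse per cycle) at Gaussian phases
(SD = cycle/8). Base theta synapses (AMPA only, non-plastic) are active for
the whole 10 s; place theta synapses (AMPA+NMDA, plastic) and a calibrated
asymmetric somatic ramp (slow rise over 80% of the window, fast fall; peak
depolarization calibrated to 4 mV) are active in the 3–8 s place window.
The rate readout is the spike train convolved with a normalized 300 ms-SD
Gaussian. After the induction pass the updated model is re-run with
plasticity frozen, and the profile RMSE against baseline is the stability
measure.

## The reduced preset

Full-scale conditions (an 809-compartment reconstruction, 303 synapses,
1–50 Hz x 10 trials, 151/61 theta synapses) take hours per protocol;
`full_preset()` encodes them for opt-in use with a user-supplied SWC file.
`reduced_preset()` is the tested desk-scale configuration. It keeps every
biophysical constant, the 25 us step, the plasticity rule and the protocol
logic, and shrinks only problem sizes: a synthetic morphology (~47
compartments, full 425 um apical extent), ~21 synapses over the same
12.5–286.7 um window, stimulus grid 2–20 Hz in 2 Hz steps with 3 trials,
25 s induction, 7 available iterations, and 12 base + 5 place theta
synapses.

Scaling down a conductance-based neuron is not merely a matter of shrinking
counts, because excitability does not scale with size. Four calibration
choices were made once, when the reduced preset was designed, and are part
of the preset definition:

* **Total synaptic budget.** Per-synapse EPSP targets are set so the
  *summed* unitary somatic EPSP amplitude is 100 mV (~4.8 mV per synapse),
  preserving the aggregate drive of 303 weak synapses with ~20 strong ones.
  With per-synapse targets at full-scale values the miniature cell barely
  responds to its stimulus grid.
* **Faster delayed rectifier** (`a0 = 0.1 /ms`). With the slow literature
  value the miniature cell cannot repolarize against sustained drive and
  enters depolarization block already at baseline; the faster rate restores
  a type-I, monotone baseline I/O profile (~10 Hz at 2 Hz drive rising to
  ~75 Hz at 20 Hz) while leaving block available at post-LTP drive levels —
  which is the phenomenon under study, not an artifact to remove.
* **T-type availability** (inactivation V1/2 at -85 mV). With more
  availability at rest, the high local input impedance of the small
  dendrites lets single EPSPs trigger calcium-driven spikes, producing
  spurious firing at very low stimulus frequencies.
* **Theta-variant rectifier.** The reduced place-field model keeps
  gKDR = 10 mS/cm^2 rather than the full-scale theta value of 2 mS/cm^2,
  again to avoid baseline block; `full_preset()` restores 2. Base and place
  theta synapses have separate EPSP targets (0.6 and 6 mV) so that a handful
  of place synapses can stand in for 61 while the base population produces a
  2–5 mV subthreshold theta oscillation with sparse out-of-field firing.

What the reduced model reproduces, and the tests assert: the left shift of
the I/O profile after LTP-dominated induction and the progressive collapse
of firing over repeated iterations; the inverted-bell RMSE-versus-slope
curve with an interior optimum; per-iteration homeostasis under the
re-optimized coupling with the optimal slope falling across iterations;
the decrease of the optimal slope with baseline synaptic scale and with
baseline HCN conductance; the information cost of homeostasis (MI at or
below baseline, the deficit carried by rising noise entropy at approximately
conserved response entropy); and place-field collapse/restoration. What it
does not reproduce: full-scale quantitative values (its optimal slopes are
grid-scale ~10 for the Poisson protocol and ~2.5 for the place protocol,
not the full-scale 3.5 and 1.1), within-induction damping of the weight
trajectory by the coupling (the shunt at dendritic operating voltages is too
small at this scale; the damping appears across iterations as smaller
cumulative permeability growth), and any statement about real neurons beyond
the mechanism itself — the generator makes no attempt to emulate full
branching statistics, synaptic jitter beyond Poisson/theta timing, or
channel noise.

## Numerical choices and degenerate inputs

* Backward Euler is unconditionally stable on the cable; accuracy at the
  fixed 25 us step is checked against an adaptive reference integrator on
  single-compartment subproblems (spike count within +-1 over 1 s) and
  against the analytic sealed-end cable solution for a passive cylinder
  (input resistance within 1%).
* Gate tables span -150..70 mV at 0.05 mV with linear interpolation and
  clamped ends; the HCN activation table is indexed by v minus the local
  half-activation voltage.
* GHK expressions use the series limit for |zFv/RT| < 1e-5, making the
  current continuous (and equal to P z F (Ci - Co)) at v = 0.
* Zero-rate Poisson trains, empty event lists, zero-amplitude ramps,
  single-point slope grids (returned as flagged boundaries) and zero-SD
  response rows (delta distributions) are all defined, tested cases.
* A calcium shell update that would cross zero clamps at zero with a
  warning; an HCN update that would cross zero clamps at a configurable
  floor with a warning; non-finite voltages abort with the first offending
  time.

## Known limitations

* The engine is a fixed-step integrator; there is no variable-step or
  network mode.
* Plasticity is restricted to AMPA/NMDA weights plus the HCN coupling;
  KA/CaT plasticity and NMDA kinetic plasticity are out of scope.
* The synthetic morphology is a single-trunk caricature; regenerative
  dendritic events (Na/Ca/NMDA spikes) are not analyzed.
* Democracy tuning assumes subthreshold EPSPs; targets close to spike
  threshold fail loudly rather than being silently clipped.
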