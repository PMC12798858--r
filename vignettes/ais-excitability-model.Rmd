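---
title: "Modelling axon-initial-segment control of the fast-spiking firing threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling axon-initial-segment control of the fast-spiking firing threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Cortical fast-spiking (parvalbumin-expressing) interneurons convert excitatory
input into inhibitory output with millisecond precision. The action potential
(AP) is initiated in the axon initial segment (AIS), and two AIS properties
differ systematically between human and mouse cells: human AISs are longer,
and they are nearly devoid of the low-voltage-activated potassium channel
Kv1.1. `aispike` implements a conductance-based multi-compartment model of
such a neuron in which the AIS geometry (length, distance from the soma) and
its channel complement (Nav1.6 and Kv1 densities) are free parameters, along
with the stimulation protocols and the operational feature definitions needed
to measure how these parameters move the AP firing threshold and the
excitation-to-spike time lag.

## Model structure

The cell has three sections: a point soma (25 pF, 700 M&#937; leak resistance,
leak reversal −68 mV), a 140 µm × 0.8 µm cylindrical axon, and a
200 µm × 1 µm cylindrical dendrite. Specific capacitance is 6 fF/µm² for the
axon and 12 fF/µm² for the dendrite. Axial resistance is expressed per unit
cable length: a stretch of axon of length *dx* µm contributes
*dx* × Ra M&#937; in series, with Ra = 0.9 M&#937;/µm at 0.8 µm diameter.
We read the three-section description as spatially discretized cables
(default axon segments 2 µm, dendrite segments 10 µm) rather than three
isopotential compartments, because the AIS must occupy a movable window
(default 10–30 µm from the soma) on the axon for positional sweeps to be
meaningful. The discretization is validated by convergence tests: halving
the axon segment length moves the measured threshold by less than 0.2 mV.

Each ionic current follows
$$I_i = g_i\, m_i^{p}\, h_i\, (E_i - V),$$
with first-order gates relaxing as $dx/dt = (x_\infty(V) - x)/\tau_x(V)$,
sigmoidal steady states
$x_\infty(V) = \tfrac12 + \tfrac12\tanh((V - V_{1/2})/V_{sl})$ and
bell-shaped time constants
$\tau_x(V) = (\tau_{max}-\tau_{min})(1-\tanh^2((V-V_{\tau,1/2})/V_{\tau,sl})) + \tau_{min}$.
The channel complement is: Nav1.6 and Kv1 in the AIS (both 20 nS/µm² under
standard, mouse-like conditions), Nav1.2 in the soma and the proximal 20% of
the dendrite, Kv3 in AIS, soma and dendrite, and leak, M-type and Kir
potassium currents plus Ih in soma and dendrite. Inward rectification (Kir)
and HCN activation (Ih) use the same formalism with a negative slope factor.

### Where the kinetic constants come from

The gating midpoints, slopes and time-constant bounds of this channel set
are not uniquely determined by any single published table; we ship a default
parameter file (`inst/params/channels.yaml`) whose values start from
standard fast-spiking basket-cell modelling ranges (low-threshold axonal
Nav1.6 with more depolarized somatic Nav1.2, slow low-voltage Kv1, fast
high-voltage Kv3, slow M/Kir/Ih background currents) and were then
calibrated, once, so that the standard-configuration cell reproduces the
baseline physiology: AP threshold near −43 mV measured with the 10 mV/ms
phase-plot criterion, input resistance and apparent membrane time constant
inside the human interquartile ranges, and rheobase near 100–150 pA. Every
constant can be overridden from a YAML config, and
`calibrate_baseline()` re-runs the (deterministic, coordinate-descent)
calibration against user-supplied targets. Two consequences of this
calibration are worth stating explicitly:

* the Nav1.6 activation curve is shallower than classic single-cell fits
  (tanh slope ≈ 17 mV, i.e. Boltzmann slope ≈ 8 mV). This is the feature
  that gives the AIS-length sweep its large dynamic range: threshold moves
  by several millivolts per doubling of AIS Na⁺ channel count only if the
  activation foot is shallow;
* Na⁺ inactivation is engaged at subthreshold voltages, so slowly
  depolarizing (near-rheobase) approaches see a partially inactivated AIS.
  This makes the threshold mildly dependent on how far above rheobase the
  readout sweep sits, which is why the standard threshold measurement is
  pinned to a fixed, just-suprathreshold margin (below).

## Numerical scheme

Gates advance by exponential Euler (exact under clamped voltage — this is
tested against the closed-form relaxation to 10⁻⁶ relative error); the
voltage system is advanced implicitly each step with a Hines elimination
over the compartment tree, with conductances frozen at the updated gate
values. The default step is dt = 0.01 ms; halving it moves the measured
threshold by under 0.1 mV. The integrator is compiled (Rcpp) because the
sweep experiments integrate a few thousand 250-ms protocols.

The holding state at −70 mV is obtained by Newton iteration on the full
nonlinear cable steady state with the somatic voltage clamped (the residual
somatic current is the holding bias), verified by relaxation, and followed
by a 200-ms settling period that is discarded. All sweeps of a protocol
start from the identical settled state.

## Operational feature definitions

The AP threshold is the membrane potential at which the somatic rise speed
first reaches 10 mV/ms, read from the phase plot (dV/dt vs V, central
differences, no smoothing) with linear interpolation between samples. An
event only counts as an AP if its peak exceeds −10 mV; this validation level
rejects stimulus-onset transients and subthreshold humps, and the threshold
crossing attributed to an AP is the *last* upward criterion crossing before
its peak, so a fast step onset cannot masquerade as spike initiation.
Half-width is measured at 50% of the threshold-to-peak amplitude, the AHP
from threshold to the post-spike trough (reported missing when the trough
is truncated or above threshold), maximal rise/fall speeds as phase-plot
extrema, and the initial rise slope as the steepest phase-plot segment
between the criterion point and the phase-plot peak. Input resistance is
the mean steady-state deflection per injected current over subthreshold
sweeps (final 20% of the step; sweeps containing APs are excluded with a
warning), and the apparent time constant comes from a single-exponential
least-squares fit to the ascending phase.

### The standard threshold measurement

Sweep experiments measure threshold as follows: find the rheobase of a
250-ms square pulse by bisection at 1 pA resolution (brackets grown from
0/100 pA, cap 1000 pA), then read the threshold from the first AP of a
sweep at rheobase + 2 pA. The fixed 2 pA margin is a numerical-conditioning
choice: exactly at rheobase the AP latency diverges and the criterion
crossing becomes ill-conditioned (the measured threshold can move by
>1 mV within the bisection's own resolution), while two picoamps above it
the readout is stable to <0.1 mV. The margin is a package default, not a
tuning knob, and is applied identically at every grid point.

## The stimulation protocols

Square current steps (250 ms for threshold work, 500 ms for recording-style
protocols) from a −70 mV holding potential, and somatic synaptic
conductances: a dual-exponential EPSC with 0.5 ms time to peak, 3 ms decay,
0 mV reversal, normalized so its maximum equals the requested peak
conductance exactly. The dual exponential is the minimal form honouring the
stated rise and decay; the rise constant is solved numerically from the
time-to-peak condition. EPSC threshold searches walk the 6–11 nS series in
0.25 nS steps and report the first conductance that elicits an AP, plus the
EPSC-onset-to-AP-onset lag for every suprathreshold strength.

## Sweep experiments and what they reproduce

With all other parameters standard, the package's sweep layer reproduces
the qualitative AIS structure-function results: lengthening the AIS from
10 to 30 µm lowers the threshold by roughly 7–8 mV (total AIS conductance
scales linearly with length); raising AIS Kv1 density from 0 to
20 nS/µm² raises it by roughly 2–3 mV; a more distal AIS start lowers it;
and lower-threshold configurations fire earlier in response to a fixed
8.5 nS EPSC (positive rank correlation between threshold and lag across
the length × density grid). The heatmap grids default to 10–30 µm ×
0–20 nS/µm² in steps of 2.5, spanning the published panel axes.

Two reproductions deserve an honest caveat. First, the published gKv1
series is not internally monotone against the published baseline (the
15 nS/µm² point sits above the 20 nS/µm² standard condition); a
physically monotone model cannot match both ends of that series to better
than about 1 mV simultaneously, and we chose to keep monotonicity. Second,
the published diameter sweep implies that adding AIS membrane (with its
proportional Na⁺ *and* K⁺ channels) *raises* threshold while adding AIS
length *lowers* it by much more; under in-place conductance scaling in a
discretized cable these two numbers constrain the same local derivative,
and no parameterization we found satisfies both with the printed
magnitudes. The geometry sweep therefore reproduces the Ra-alone bound
(<1 mV) and the orderings, while the absolute narrow-axon threshold is
closer to baseline than the printed value. Both caveats are visible as
documented tolerances in the test suite rather than hidden by relaxed
checks.

## The synthetic-data module

`synth_ap_trace()` builds AP trains from sums of logistic components on an
exponential charging baseline. The upstroke width is solved so that the
closed-form derivative crosses 10 mV/ms exactly at the programmed threshold
potential, and the amplitude so the waveform maximum equals the programmed
peak; the annotations carry these exact crossings (computed by root-finding
on the analytic derivative, not from sampled data), which makes the
detector's oracle exact rather than numeric. The resulting upstroke is
slower than a real fast-spiking AP (a single logistic cannot place a
10 mV/ms crossing a few millivolts above baseline *and* reach a 250 mV/ms
peak rise), so the templates validate threshold/latency/count/AHP logic,
not maximal rise speeds; rise-speed features are exercised on simulated
traces instead. `synth_passive_trace()` produces exact RC charging with
known Rin and tau. `synth_cohort()` draws per-cell feature vectors from
quantile-matched shifted log-normal distributions (mirrored for
left-skewed features, normal when the quartiles are symmetric), matching
the bundled human/mouse median/IQR targets; the log-normal family supports
the skew those targets exhibit, and the family is pluggable. All synthetic
randomness flows through explicit seeds via a local RNG that leaves the
global stream untouched. What passing synthetic tests show is that the
measurement code recovers known ground truth; they do not certify the
biophysical model itself, which is instead checked against the published
sweep anchors.

## Problem sizes and determinism

The bundled experiments are desk-scale by construction: the standard cell
discretizes to 91 compartments, a 250-ms protocol at dt = 0.01 ms is
25,000 steps, a full 9 × 9 threshold heatmap is ~10³ integrations and runs
in minutes on one core. Simulations contain no randomness; sweep outputs
are bit-identical across runs for a fixed configuration and package
version, and the run manifest records the config digest and seeds of any
synthetic stages.

## Known limitations

* The kinetic constants are calibrated, not measured; they are one
  consistent set reproducing the target physiology, not a claim about the
  underlying channels. Temperature dependence, stochastic gating and
  Markov-state channel behaviour are out of scope.
* The morphology is deliberately minimal (three sections); myelin,
  branch-point effects and reconstructed morphologies are not represented,
  and the AIS is assumed uniform along its length.
* The EPSC enters at the soma only, matching the simulated protocol it
  reproduces; dendritic synapse placement is not implemented.
* Cohort synthesis matches marginal quantiles only; cross-feature
  correlations present in real cells are not emulated, and because only the
  quartiles are constrained, distribution tails are not: for features whose
  interquartile range is wide relative to the median (e.g. input
  resistance), extreme draws can leave the physically meaningful range.
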