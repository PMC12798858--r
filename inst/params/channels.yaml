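# Default channel kinetics for the fast-spiking interneuron model.
#
# Formalism: x_inf(V) = 1/2 + 1/2*tanh((V - v_half)/v_slope)
#            tau_x(V) = (tau_max - tau_min)*(1 - tanh((V - v_tau_half)/v_tau_slope)^2) + tau_min
# Units: mV, ms.  The tanh slope equals twice the Boltzmann slope factor.
# A negative v_slope gives a steady state that falls with depolarization
# (inactivation gates, inward rectification, HCN activation).
#
# These constants start from standard fast-spiking basket-cell modelling
# ranges (low-threshold axonal Nav1.6, higher-threshold somatic Nav1.2, slow
# low-voltage Kv1, fast high-voltage Kv3, slow M/Kir/Ih background currents)
# and were calibrated once so the standard-configuration cell reproduces the
# baseline firing threshold and step-response physiology; see the package
# vignette for the calibration rationale. Every value can be overridden from
# a model config file.

channels:
  Nav1.6:
    p: 3
    e_rev: 55
    activation:   {v_half:  -31.36, v_slope:   17.59, tau_max: 0.12, tau_min: 0.04, v_tau_half:  -35.36, v_tau_slope: 25.0}
    inactivation: {v_half:  -55.05, v_slope:  -25.83, tau_max:       2, tau_min: 0.3, v_tau_half:  -52.05, v_tau_slope: 25.0}
  Nav1.2:
    p: 3
    e_rev: 55
    activation:   {v_half:  -18.36, v_slope:   17.59, tau_max: 0.12, tau_min: 0.04, v_tau_half:  -22.36, v_tau_slope: 25.0}
    inactivation: {v_half:  -42.05, v_slope:  -25.83, tau_max:       2, tau_min: 0.3, v_tau_half:  -39.05, v_tau_slope: 25.0}
  Kv1:
    p: 1
    e_rev: -90
    activation:   {v_half:  -24.98, v_slope:    9.46, tau_max:    7.04, tau_min: 1.0, v_tau_half: -50.0, v_tau_slope: 40.0}
  Kv3:
    p: 2
    e_rev: -90
    activation:   {v_half: -9.0, v_slope: 17.0, tau_max: 1.4, tau_min: 0.2, v_tau_half: -15.0, v_tau_slope: 35.0}
  M:
    p: 1
    e_rev: -90
    activation:   {v_half: -32.0, v_slope: 18.0, tau_max: 90.0, tau_min: 25.0, v_tau_half: -35.0, v_tau_slope: 40.0}
  Kir:
    p: 1
    e_rev: -90
    activation:   {v_half: -85.0, v_slope: -24.0, tau_max: 2.0, tau_min: 0.5, v_tau_half: -85.0, v_tau_slope: 40.0}
  Ih:
    p: 1
    e_rev: -35
    activation:   {v_half: -84.0, v_slope: -16.0, tau_max: 70.0, tau_min: 25.0, v_tau_half: -84.0, v_tau_slope: 40.0}

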