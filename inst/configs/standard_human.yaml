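# Standard conditions: human-calibrated fast-spiking interneuron model cell.
# Units: mV, ms, nS, pA, pF, um; axial resistance (ra) in Mohm per um of cable.
# Omitted keys fall back to the package defaults (which equal these values).

geometry:
  soma:
    cm_total: 25        # pF
    r_leak: 700         # Mohm
    e_leak: -68         # mV
  axon:
    length: 140         # um
    diameter: 0.8       # um
    segment_length: 2   # um (spatial discretization)
    cm_per_area: 6      # fF/um^2
    ra: 0.9             # Mohm/um
  dendrite:
    length: 200
    diameter: 1
    segment_length: 10
    cm_per_area: 12     # 2-fold higher than the axon
    ra: 0.58

ais:
  start: 10             # um from soma
  length: 20            # um
  gnav16_density: 20    # nS/um^2
  gkv1_density: 20      # nS/um^2 (mouse-like level; human-like AIS uses 0)

simulation:
  dt: 0.01              # ms
  v_hold: -70           # mV
  settle_ms: 200        # discarded settling time before each protocol
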