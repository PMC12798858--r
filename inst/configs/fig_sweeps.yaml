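# End-to-end sweep suite over the published AIS parameter ranges.
# Run with:  inst/cli/aispike.R sweep --config <this file> --out <dir>
# Model section: standard conditions (defaults); sweep axes below.

sweeps:
  ais_length_thresholds:
    kind: threshold
    ais_length: [10, 20, 30]
  kv1_thresholds:
    kind: threshold
    gkv1_density: [0, 5, 10, 15]
  ais_start_thresholds:
    kind: threshold
    ais_start: [0, 10]
  threshold_heatmap:
    kind: threshold
    ais_length: [10, 12.5, 15, 17.5, 20, 22.5, 25, 27.5, 30]
    gkv1_density: [0, 2.5, 5, 7.5, 10, 12.5, 15, 17.5, 20]
  epsc_lag_heatmap:
    kind: epsc_lag
    g_peak: 8.5
    ais_length: [10, 12.5, 15, 17.5, 20, 22.5, 25, 27.5, 30]
    gkv1_density: [0, 2.5, 5, 7.5, 10, 12.5, 15, 17.5, 20]
  diameter_physical:
    kind: geometry
    mode: physical
    diameters: [0.6, 0.7, 0.8, 0.9]
    ra: [1.1, 1.0, 0.9, 0.8]
  ra_alone:
    kind: geometry
    mode: ra_only
    ra: [0.8, 0.95, 1.1]
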