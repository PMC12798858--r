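# phase plot, AP detection, waveform features, passive measurements

test_that("phase plot differentiates simple analytic traces correctly", {
  dt <- 0.05
  tt <- seq(0, 20, by = dt)
  # linear ramp: dV/dt constant
  ramp <- voltage_trace(tt, -70 + 2 * tt)
  pp <- phase_plot(ramp)
  expect_true(all(abs(pp$dvdt - 2) < 1e-9))
  expect_equal(nrow(pp), length(tt) - 2)
  # constant trace: all zero
  expect_true(all(phase_plot(voltage_trace(tt, rep(-70, length(tt))))$dvdt == 0))
  # sinusoid: max dV/dt = omega x amplitude within discretization error
  om <- 2
  sin_tr <- voltage_trace(tt, -60 + 5 * sin(om * tt))
  expect_equal(max(phase_plot(sin_tr)$dvdt), 5 * om, tolerance = 1e-2)
  expect_error(phase_plot(voltage_trace(0, -70)), "3 samples")
})

test_that("detector recovers programmed thresholds from synthetic APs", {
  spec <- synthetic_cell_spec(threshold = -41.0, peak = 12, noise_sd = 0)
  tr <- synth_ap_trace(spec, dt = 0.01)
  aps <- detect_aps(tr)
  expect_equal(nrow(aps), 1)
  # within one inter-sample voltage increment of the programmed crossing
  gt <- tr$meta$ground_truth[[1]]
  expect_equal(gt$v, -41.0, tolerance = 1e-6)
  dv_samp <- max(abs(diff(tr$v_soma[abs(tr$time - gt$t) < 0.05])))
  expect_lt(abs(aps$v_threshold - (-41.0)), dv_samp)
  # peak recovered
  expect_equal(aps$v_peak, gt$v_peak, tolerance = 0.05)
  # flat trace: empty detection
  expect_equal(nrow(detect_aps(voltage_trace(seq(0, 50, 0.01),
                                             rep(-70, 5001)))), 0)
})

test_that("detection ignores stimulus-onset transients and subthreshold humps", {
  # ramp with initial fast transient exceeding the criterion but peaking low
  dt <- 0.01
  tt <- seq(0, 60, by = dt)
  v <- -70 + 25 * (tt > 5) * (1 - exp(-(pmax(tt - 5, 0)) / 1.2)) # 20 mV/ms onset
  expect_equal(nrow(detect_aps(voltage_trace(tt, v))), 0)
  # add a genuine AP late in the trace: only that AP is reported, with its
  # own upstroke crossing (not the onset transient)
  spec <- synthetic_cell_spec(threshold = -38.9, peak = 15.6, noise_sd = 0)
  ap <- synth_ap_trace(spec, dt = dt, onset = 5, first_ap_latency = 30,
                       total_ms = 60)
  aps <- detect_aps(ap)
  expect_equal(nrow(aps), 1)
  expect_gt(aps$t_threshold, 20)
  expect_equal(aps$v_threshold, -38.9, tolerance = 0.15)
})

test_that("triangular-spike geometry yields the textbook half-width", {
  # symmetric triangular spike, threshold -40 to peak +10 over 1 ms each side
  dt <- 0.001
  up <- seq(-40, 10, by = 50 * dt)      # 50 mV/ms rise
  down <- seq(10, -40, by = -50 * dt)
  v <- c(rep(-40, 300), up, down[-1], rep(-40, 300))
  tt <- seq_along(v) * dt
  tr <- voltage_trace(tt, v)
  aps <- detect_aps(tr, criterion = 10)
  fx <- ap_features(tr, aps[1, ])
  # half level at -15 mV; crossings 1 ms apart
  expect_equal(fx$half_width, 1.0, tolerance = 0.02)
  expect_equal(fx$max_rise, 50, tolerance = 1e-6)
  expect_equal(fx$max_fall, -50, tolerance = 1e-6)
})

test_that("AP features report AHP against threshold and flag missing troughs", {
  spec <- synthetic_cell_spec(threshold = -38.9, peak = 15.6, ahp_depth = 19.7)
  tr <- synth_ap_trace(spec, dt = 0.01)
  aps <- detect_aps(tr)
  fx <- ap_features(tr, aps[1, ])
  expect_equal(fx$ahp_amplitude, -19.7, tolerance = 0.6)
  expect_lt(fx$max_fall, 0)
  expect_gt(fx$initial_rise_slope, 0)
  # truncate the trace before the trough: AHP missing, not fabricated
  cut <- which(tr$time > aps$t_peak + 0.05)[1]
  tr2 <- voltage_trace(tr$time[1:cut], tr$v_soma[1:cut])
  aps2 <- detect_aps(tr2)
  expect_equal(nrow(aps2), 1)
  expect_true(is.na(aps2$v_trough))
  expect_true(is.na(ap_features(tr2, aps2[1, ])$ahp_amplitude))
})

test_that("latency and spike count follow the programmed train", {
  spec <- synthetic_cell_spec(threshold = -38.9, peak = 15.6)
  tr <- synth_ap_trace(spec, dt = 0.01, n_aps = 5, onset = 10,
                       first_ap_latency = 19.6, isi = 15)
  lc <- latency_and_count(tr, step_onset = 10)
  expect_equal(lc$spike_count, 5L)
  expect_equal(lc$latency, 19.6, tolerance = 0.05)
  # two APs at programmed 10 and 20 ms latencies
  tr2 <- synth_ap_trace(spec, dt = 0.01, n_aps = 2, onset = 5,
                        first_ap_latency = 10, isi = 10)
  lc2 <- latency_and_count(tr2, step_onset = 5)
  expect_equal(lc2$spike_count, 2L)
  expect_equal(lc2$latency, 10, tolerance = 0.05)
  # empty trace
  flat <- voltage_trace(seq(0, 100, 0.05), rep(-70, 2001))
  lc0 <- latency_and_count(flat, step_onset = 10)
  expect_true(is.na(lc0$latency))
  expect_equal(lc0$spike_count, 0L)
})

test_that("Rin measurement averages sweeps and excludes spiking sweeps", {
  tr <- synth_passive_trace(rin = 188, tau = 6.6, step_pA = 50)
  expect_equal(as.numeric(measure_rin(tr)), 188, tolerance = 1e-3)
  tr2 <- synth_passive_trace(rin = 188, tau = 6.6, step_pA = 80)
  expect_equal(as.numeric(measure_rin(list(tr, tr2))), 188, tolerance = 1e-3)
  # a sweep with an AP is excluded with a warning
  sp <- synth_ap_trace(synthetic_cell_spec(), dt = 0.01)
  expect_warning(r3 <- measure_rin(list(tr, sp)), "excluded")
  expect_equal(as.numeric(r3), 188, tolerance = 1e-3)
  expect_error(suppressWarnings(measure_rin(list(sp))), "excluded")
})

test_that("tau fit recovers programmed and noisy time constants", {
  tr <- synth_passive_trace(rin = 187.9, tau = 6.65, step_pA = 50)
  expect_equal(as.numeric(measure_tau(tr)), 6.65, tolerance = 0.01)
  trn <- synth_passive_trace(rin = 187.9, tau = 6.65, step_pA = 50,
                             noise_sd = 0.2, seed = 11)
  expect_equal(as.numeric(measure_tau(trn)), 6.65, tolerance = 0.05)
})

test_that("feature extraction is stable under doubled sampling rate", {
  spec <- synthetic_cell_spec(threshold = -38.9, peak = 15.6)
  f1 <- trace_features(synth_ap_trace(spec, dt = 0.02))
  f2 <- trace_features(synth_ap_trace(spec, dt = 0.01))
  expect_lt(abs(f1$threshold - f2$threshold), 0.2)
  expect_lt(abs(f1$half_width - f2$half_width) / f2$half_width, 0.02)
})
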