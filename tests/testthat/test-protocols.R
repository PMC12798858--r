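# stimulation protocols: EPSC waveform shape, step sweeps, rheobase search

test_that("EPSC waveform peaks exactly at g_peak at onset + time-to-peak", {
  p <- epsc_protocol(onset = 5)
  dt <- 0.01
  g <- epsc_conductance_waveform(p, g_peak = 8.5, dt = dt, total_ms = 40)
  tt <- seq_along(g) * dt
  expect_equal(max(g), 8.5, tolerance = 1e-12)   # normalized to machine precision
  expect_equal(tt[which.max(g)], 5.5, tolerance = dt / 2 + 1e-9)
  # causality: zero at and before onset
  expect_true(all(g[tt <= 5] == 0))
  # ~e-fold decay 3 ms after the peak (rise term negligible by then)
  g_at <- g[which.min(abs(tt - 8.5))]
  expect_equal(g_at, 8.5 * exp(-1), tolerance = 8.5 * exp(-1) * 0.02)
  # undersampled rise is an error
  expect_error(epsc_conductance_waveform(p, 8.5, dt = 0.6), "undersample")
})

test_that("step sweeps start from identical holding state and scale passively", {
  cell <- passive_cell()
  trs <- run_step_protocol(cell, step_protocol(c(0, 50), duration = 250,
                                               onset = 10), dt = 0.02)
  expect_length(trs, 2)
  expect_equal(trs[[1]]$v_soma[1], trs[[2]]$v_soma[1])
  expect_lt(max(abs(trs[[1]]$v_soma + 70)), 0.1)   # flat at 0 pA
  # steady deflection = amplitude x input resistance
  rin <- as.numeric(measure_rin(trs[[2]]))
  i1 <- max(which(trs[[2]]$i_stim != 0))
  dv <- trs[[2]]$v_soma[i1] - (-70)
  expect_equal(dv, 50 * rin / 1000, tolerance = 0.02)
})

test_that("rheobase search fails cleanly on a passive cell", {
  expect_error(find_rheobase(passive_cell(), duration = 60, bracket_max = 400,
                             dt = 0.05), "no rheobase")
})

test_that("bisection rheobase equals the exhaustive grid scan", {
  cell <- standard_cell()
  hold <- aispike:::.settled_state(cell, -70)
  rh <- find_rheobase(cell, duration = 80, resolution = 1, hold = hold)
  # brute force: scan 1 pA steps around the bisection result
  spikes_at <- function(amp) {
    tr <- aispike:::.step_sweep(cell, hold, amp, 80, 5, 0.01)
    nrow(detect_aps(tr)) > 0
  }
  amps <- seq(floor(as.numeric(rh)) - 3, ceiling(as.numeric(rh)) + 1, by = 1)
  hits <- vapply(amps, spikes_at, logical(1))
  grid_rheo <- amps[which(hits)[1]]
  expect_lte(abs(as.numeric(rh) - grid_rheo), 1)
  # monotonicity: extra AIS Nav1.6 cannot raise rheobase
  more_na <- modify_cell(cell, gnav16_density = 26)
  rh2 <- find_rheobase(more_na, duration = 80, resolution = 1)
  expect_lte(as.numeric(rh2), as.numeric(rh))
})

test_that("EPSC threshold search returns the first spiking conductance and lags", {
  cell <- standard_cell()
  p <- epsc_protocol(peak_conductances = c(0.001))
  r0 <- find_threshold_epsc(cell, p)
  expect_true(is.na(r0$g_threshold))
  p2 <- epsc_protocol(peak_conductances = seq(2, 20, by = 0.5))
  r <- find_threshold_epsc(cell, p2)
  expect_false(is.na(r$g_threshold))
  sup <- r$lags[r$lags$spike, ]
  expect_true(all(sup$g_peak_nS >= r$g_threshold))
  # AP lag is non-increasing with EPSC strength
  expect_true(all(diff(sup$lag_ms) < 1e-9))
  # descending conductances rejected
  expect_error(find_threshold_epsc(cell,
    epsc_protocol(peak_conductances = c(8, 7))), "ascending")
})
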