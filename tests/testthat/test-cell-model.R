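# cell assembly, discretization, holding bias, passive cable physics

test_that("standard geometry discretizes as expected and AIS spans its window", {
  cell <- standard_cell()
  expect_equal(sum(cell$comp$section == "axon"), 70)  # 140 um at 2 um
  ais <- cell$idx$ais
  centres <- cell$comp$x0[ais] + cell$comp$len[ais] / 2
  expect_true(all(centres >= 10 & centres <= 30))
  expect_length(ais, 10)
  # per-segment AIS conductance: density x pi x diameter x segment length
  expect_equal(unname(cell$gbar[ais[1], "Nav1.6"]), 20 * pi * 0.8 * 2,
               tolerance = 1e-10)
  expect_equal(sum(cell$gbar[, "Nav1.6"]), 20 * pi * 0.8 * 20, tolerance = 1e-10)
  # total AIS conductance scales linearly with AIS length
  c30 <- modify_cell(cell, ais_length = 30)
  expect_equal(sum(c30$gbar[, "Kv1"]) / sum(cell$gbar[, "Kv1"]), 1.5,
               tolerance = 1e-10)
})

test_that("invalid geometry is rejected with informative errors", {
  expect_error(build_cell(cell_config(ais = list(start = 130, length = 20))),
               "ais")
  expect_error(build_cell(cell_config(ais = list(gkv1_density = -5))),
               "gkv1_density")
  expect_error(build_cell(cell_config(geometry = list(axon = list(
    segment_length = 200)))), "segment_length")
})

test_that("holding bias on the passive isolated soma follows Ohm's law", {
  cell <- isolated_soma_cell()
  bias <- solve_holding_bias(cell, -70)
  # (V_hold - E_leak) / R = -2 mV / 700 Mohm = -2.857 pA
  expect_equal(as.numeric(bias), -2000 / 700, tolerance = 1e-6)
  # at the resting potential the bias vanishes
  expect_lt(abs(as.numeric(solve_holding_bias(cell, -68))), 1e-6)
})

test_that("passive isolated soma charging matches the RC closed form", {
  cell <- isolated_soma_cell()
  tr <- run_step_protocol(cell, step_protocol(10, duration = 120, onset = 10),
                          dt = 0.01)[[1]]
  # R = 700 Mohm, C = 25 pF: dV_ss = 7 mV, tau = 17.5 ms
  stepw <- tr$time > 10 & tr$time <= 130
  pred <- -70 + 7 * (1 - exp(-(tr$time[stepw] - 10) / 17.5))
  expect_lt(max(abs(tr$v_soma[stepw] - pred)), 0.07)  # within 1% of dV_ss
  expect_equal(as.numeric(measure_tau(tr)), 17.5, tolerance = 0.02)
  expect_equal(as.numeric(measure_rin(tr)), 700, tolerance = 0.01)
})

test_that("passive cable input resistance matches the linear-algebra oracle", {
  cell <- passive_cell()
  v <- passive_steady_oracle(cell, i_soma_pA = 10)
  v0 <- passive_steady_oracle(cell, i_soma_pA = 0)
  rin_oracle <- (v[1] - v0[1]) / 10 * 1000
  tr <- run_step_protocol(cell, step_protocol(10, duration = 400, onset = 10),
                          dt = 0.02)[[1]]
  rin_sim <- as.numeric(measure_rin(tr))
  expect_equal(rin_sim, rin_oracle, tolerance = 0.02)
  # full steady-state voltage profile agrees compartment by compartment
  bias <- solve_holding_bias(passive_cell(), -70, verify = FALSE)
  st <- attr(bias, "state")
  v_or <- passive_steady_oracle(cell, as.numeric(bias))
  expect_lt(max(abs(st$v - v_or)), 1e-6)
})

test_that("zero-amplitude protocol stays at holding and channel currents have the driving-force sign", {
  cell <- standard_cell()
  tr <- integrate_cell(cell, list(kind = "step", amplitude = 0, onset = 5,
                                  duration = 50, total_ms = 60))
  expect_lt(max(abs(tr$v_soma - (-70))), 0.1)
  # sign sanity: each gated current has the sign of (E - V)
  ch <- cell$channels
  for (nm in c("Nav1.6", "Kv1", "Kv3")) {
    sp <- ch[[nm]]
    for (v in c(-80, -50, -10, 40)) {
      m <- steady_state(v, sp$activation)
      i <- channel_current(v, 100, m = m,
                           h = if (is.null(sp$inactivation)) 1
                               else steady_state(v, sp$inactivation),
                           spec = sp)
      if (abs(v - sp$e_rev) > 1e-9) expect_equal(sign(i), sign(sp$e_rev - v))
    }
  }
})

test_that("integration reports divergence rather than returning garbage", {
  cell <- standard_cell()
  # a non-physical stimulus drives |Vm| past the 200 mV guard
  expect_error(
    integrate_cell(cell, list(kind = "step", amplitude = 1e9, onset = 1,
                              duration = 40, total_ms = 45)),
    "divergence|diverged")
})
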