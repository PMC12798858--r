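# gating kinetics: sigmoid steady state, bell-shaped tau, relaxation ODE,
# ohmic channel current

k_fast <- gate_kinetics(v_half = -43, v_slope = 12, tau_max = 0.2,
                        tau_min = 0.04, v_tau_half = -45, v_tau_slope = 30)

test_that("steady state is a tanh sigmoid with the expected anchors", {
  expect_equal(steady_state(-43, k_fast), 0.5)
  expect_equal(steady_state(1e4, k_fast), 1)
  expect_equal(steady_state(-1e4, k_fast), 0)
  # odd symmetry about the midpoint
  for (d in c(1, 7.3, 25))
    expect_equal(steady_state(-43 + d, k_fast) + steady_state(-43 - d, k_fast), 1)
  # monotone increasing for positive slope, decreasing for negative
  v <- seq(-120, 40, by = 0.5)
  expect_true(all(diff(steady_state(v, k_fast)) > 0))
  k_inact <- gate_kinetics(-60, -10, 2, 0.3)
  expect_true(all(diff(steady_state(v, k_inact)) < 0))
})

test_that("steady state and tau are invariant under (V - centre, slope) sign flip", {
  k_neg <- gate_kinetics(-43, -12, 0.2, 0.04, -45, -30)
  v <- seq(-100, 20, by = 2.5)
  expect_equal(steady_state(v, k_fast), steady_state(-86 - v, k_neg))
  expect_equal(time_constant(v, k_fast), time_constant(-90 - v, k_neg))
})

test_that("time constant is bell-shaped, bounded and peaks at its midpoint", {
  expect_equal(time_constant(-45, k_fast), 0.2)
  expect_equal(time_constant(1e4, k_fast), 0.04)
  expect_equal(time_constant(-1e4, k_fast), 0.04)
  # closed form at unit offset: tau_min + (1 - tanh(1)^2) (tau_max - tau_min),
  # with 1 - tanh(1)^2 = 0.4199743416 (frozen from an independent evaluation)
  expect_equal(time_constant(-45 + 30, k_fast), 0.04 + 0.4199743416 * 0.16,
               tolerance = 1e-9)
  v <- seq(-120, 40, by = 0.1)
  tau <- time_constant(v, k_fast)
  expect_true(all(tau >= 0.04 & tau <= 0.2))
  expect_equal(v[which.max(tau)], -45)
})

test_that("gate derivative has the fixed-point and sign structure of first-order relaxation", {
  v <- -50
  expect_equal(gate_derivative(steady_state(v, k_fast), v, k_fast), 0)
  expect_gt(gate_derivative(0, v, k_fast), 0)
  expect_lt(gate_derivative(1, v, k_fast), 0)
  # direct substitution: x = 0, x_inf = 1, tau = 2 -> dx/dt = 0.5 /ms
  k_unit <- gate_kinetics(v_half = 0, v_slope = 1, tau_max = 2, tau_min = 2)
  expect_equal(gate_derivative(0, 1e4, k_unit), 0.5)
})

test_that("numerical gate integration matches the closed-form exponential relaxation", {
  # clamped V: x(t) = x_inf + (x0 - x_inf) exp(-t / tau)
  for (v_clamp in c(-80, -50, -20)) {
    x_inf <- steady_state(v_clamp, k_fast)
    tau <- time_constant(v_clamp, k_fast)
    x0 <- 0.9
    dt <- tau / 200
    n <- 200 # integrate to t = tau
    x <- x0
    for (i in seq_len(n)) x <- x + (x_inf - x) * (1 - exp(-dt / tau))
    exact <- x_inf + (x0 - x_inf) * exp(-1)
    expect_equal(x, exact, tolerance = 1e-6)
  }
  # piecewise-constant V: relaxation restarts from the reached state
  x <- 0.2
  v_seq <- c(-70, -30)
  expected <- 0.2
  for (v in v_seq) {
    tau <- time_constant(v, k_fast); x_inf <- steady_state(v, k_fast)
    for (i in 1:100) x <- x + (x_inf - x) * (1 - exp(-(tau / 100) / tau))
    expected <- x_inf + (expected - x_inf) * exp(-1)
  }
  expect_equal(x, expected, tolerance = 1e-6)
})

test_that("channel current is ohmic in the driving force with gating factors", {
  na <- channel_spec("Nav1.6", 20, 1, -90, activation = k_fast)
  expect_equal(channel_current(-90, 20, m = 0.7, h = 1, spec = na), 0)
  expect_equal(channel_current(-40, 20, m = 0.5, h = 1, spec = na), -500)
  # leak: p = 0, current independent of m
  leak <- channel_spec("leak", 1.5, 0, -68)
  expect_equal(channel_current(-58, 1.5, m = 0.1, h = 1, spec = leak),
               channel_current(-58, 1.5, m = 0.9, h = 1, spec = leak))
  expect_equal(channel_current(-58, 1.5, m = 0, h = 1, spec = leak), -15)
})

test_that("invalid kinetics and channel specs are rejected", {
  expect_error(gate_kinetics(-43, 0, 1, 0.1), "v_slope")
  expect_error(gate_kinetics(-43, 5, 0.1, 0.2), "tau_max")
  expect_error(gate_kinetics(-43, 5, 1, 0), "tau_min")
  expect_error(channel_spec("x", -1, 1, -90, activation = k_fast), ">= 0")
  expect_error(channel_spec("x", 1, 1, -90), "activation")
  expect_error(channel_spec("leak", 1, 0, -68, inactivation = k_fast), "leak")
})

test_that("bundled channel file loads with the expected channel set", {
  ch <- load_channels()
  expect_setequal(names(ch),
                  c("Nav1.6", "Nav1.2", "Kv1", "Kv3", "M", "Kir", "Ih"))
  expect_s3_class(ch$Nav1.6$activation, "gate_kinetics")
  expect_s3_class(ch$Nav1.6$inactivation, "gate_kinetics")
  expect_null(ch$Kv3$inactivation)
  # inward currents reverse positive, K currents at E_K
  expect_gt(ch$Nav1.6$e_rev, 0)
  expect_lt(ch$Kv1$e_rev, -80)
})
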