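#' Voltage-dependent gate kinetics
#'
#' A gate (activation `m` or inactivation `h`) is described by a sigmoid
#' steady state and a bell-shaped voltage-dependent time constant:
#' \deqn{x_\infty(V) = \tfrac12 + \tfrac12\tanh\!\left(\frac{V - V_{1/2}}{V_{sl}}\right)}
#' \deqn{\tau_x(V) = (\tau_{max}-\tau_{min})\left[1-\tanh^2\!\left(\frac{V - V_{\tau,1/2}}{V_{\tau,sl}}\right)\right] + \tau_{min}}
#' A negative `v_slope` yields a steady state that decreases with voltage
#' (inactivation gates, inward rectifiers, HCN channels).
#'
#' @param v_half midpoint of the steady-state sigmoid (mV).
#' @param v_slope slope factor of the sigmoid (mV, non-zero; sign sets
#'   direction). Note this tanh slope equals twice the Boltzmann slope factor.
#' @param tau_max,tau_min bounds of the bell-shaped time constant (ms,
#'   `tau_max >= tau_min > 0`).
#' @param v_tau_half voltage of the time-constant maximum (mV).
#' @param v_tau_slope width of the time-constant bell (mV, non-zero).
#' @return An object of class `gate_kinetics`.
#' @examples
#' k <- gate_kinetics(-43, 12, 0.2, 0.04, -45, 30)
#' steady_state(-43, k) # 0.5 at the midpoint
#' @export
gate_kinetics <- function(v_half, v_slope, tau_max, tau_min,
                          v_tau_half = v_half, v_tau_slope = abs(v_slope) * 2) {
  stopifnot(is.numeric(v_half), is.numeric(v_slope), is.numeric(tau_max),
            is.numeric(tau_min), is.numeric(v_tau_half), is.numeric(v_tau_slope))
  if (tau_min <= 0) stop("gate_kinetics: tau_min must be > 0")
  if (tau_max < tau_min) stop("gate_kinetics: tau_max must be >= tau_min")
  if (v_slope == 0) stop("gate_kinetics: v_slope must be non-zero")
  if (v_tau_slope == 0) stop("gate_kinetics: v_tau_slope must be non-zero")
  structure(list(v_half = v_half, v_slope = v_slope,
                 tau_max = tau_max, tau_min = tau_min,
                 v_tau_half = v_tau_half, v_tau_slope = v_tau_slope),
            class = "gate_kinetics")
}

#' @export
print.gate_kinetics <- function(x, ...) {
  cat(sprintf("<gate_kinetics> V1/2 %.1f mV, slope %.1f mV, tau %g-%g ms (bell at %.1f mV)\n",
              x$v_half, x$v_slope, x$tau_min, x$tau_max, x$v_tau_half))
  invisible(x)
}

#' Steady-state gate value
#'
#' @param v membrane potential (mV), vectorized.
#' @param k a [gate_kinetics()] object.
#' @return Gate open fraction in (0, 1).
#' @export
steady_state <- function(v, k) {
  stopifnot(inherits(k, "gate_kinetics"))
  0.5 + 0.5 * tanh((v - k$v_half) / k$v_slope)
}

#' Voltage-dependent gate time constant
#'
#' Bell-shaped in voltage with maximum `tau_max` at `v_tau_half` and
#' asymptote `tau_min`.
#'
#' @inheritParams steady_state
#' @return Time constant (ms), within `[tau_min, tau_max]`.
#' @export
time_constant <- function(v, k) {
  stopifnot(inherits(k, "gate_kinetics"))
  th <- tanh((v - k$v_tau_half) / k$v_tau_slope)
  (k$tau_max - k$tau_min) * (1 - th^2) + k$tau_min
}

#' First-order gate relaxation rate
#'
#' `dx/dt = (x_inf(V) - x) / tau_x(V)`.
#'
#' @param x current gate value in \[0, 1\].
#' @param v membrane potential (mV).
#' @param k a [gate_kinetics()] object.
#' @return Rate of change (1/ms).
#' @export
gate_derivative <- function(x, v, k) {
  stopifnot(all(x >= 0 & x <= 1))
  (steady_state(v, k) - x) / time_constant(v, k)
}

#' Channel specification
#'
#' An ionic current is `I = g * m^p * h * (E - V)` (positive = inward,
#' depolarizing). `p = 0` describes an ungated leak; inactivation is either
#' first-order (a second [gate_kinetics()]) or absent (`h` fixed at 1).
#'
#' @param name channel identifier (e.g. "Nav1.6", "Kv1", "leak").
#' @param density_or_total conductance; interpreted as density (nS/um^2) for
#'   distributed channels or total (nS) for point-compartment channels,
#'   depending on where the cell model places it.
#' @param p non-negative integer activation exponent.
#' @param e_rev reversal potential (mV).
#' @param activation [gate_kinetics()] for `m` (required when `p > 0`).
#' @param inactivation optional [gate_kinetics()] for `h`.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(name, density_or_total, p, e_rev,
                         activation = NULL, inactivation = NULL) {
  if (density_or_total < 0) stop("channel_spec: conductance must be >= 0")
  p <- as.integer(p)
  if (p < 0) stop("channel_spec: activation exponent p must be >= 0")
  if (p > 0 && !inherits(activation, "gate_kinetics"))
    stop("channel_spec: gated channel (p > 0) needs activation kinetics")
  if (p == 0 && !is.null(inactivation))
    stop("channel_spec: leak (p = 0) cannot have inactivation")
  if (!is.null(inactivation) && !inherits(inactivation, "gate_kinetics"))
    stop("channel_spec: inactivation must be gate_kinetics or NULL")
  structure(list(name = name, g = density_or_total, p = p, e_rev = e_rev,
                 activation = activation, inactivation = inactivation),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel_spec> %s: g = %g, p = %d, E = %g mV, inactivation: %s\n",
              x$name, x$g, x$p, x$e_rev,
              if (is.null(x$inactivation)) "absent" else "first-order"))
  invisible(x)
}

#' Instantaneous single-channel current
#'
#' @param v membrane potential (mV).
#' @param g_total total conductance (nS).
#' @param m,h gate states in \[0, 1\] (`h = 1` when inactivation absent).
#' @param spec a [channel_spec()] (supplies `p` and `e_rev`).
#' @return Current in pA, positive inward: `g_total * m^p * h * (E - V)`.
#' @export
channel_current <- function(v, g_total, m, h = 1, spec) {
  stopifnot(inherits(spec, "channel_spec"), g_total >= 0,
            all(m >= 0 & m <= 1), all(h >= 0 & h <= 1))
  g_total * m^spec$p * h * (spec$e_rev - v)
}

# Pack a list of channel_spec into the kinetics matrix consumed by sim_core.
# Rows: channels; columns: p, E, has_inact, act(6), inact(6).
.kin_matrix <- function(specs) {
  dummy <- c(0, 1, 1, 1, 0, 1) # inert placeholder for absent gates
  kin <- t(vapply(specs, function(s) {
    a <- if (is.null(s$activation)) dummy else unlist(s$activation)
    i <- if (is.null(s$inactivation)) dummy else unlist(s$inactivation)
    c(s$p, s$e_rev, as.numeric(!is.null(s$inactivation)), a, i)
  }, numeric(15)))
  rownames(kin) <- vapply(specs, `[[`, "", "name")
  kin
}
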