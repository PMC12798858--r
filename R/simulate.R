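# Simulation drivers: holding-state solution and protocol integration.

# Steady-state ionic conductance/current terms with gates at steady state.
# Returns list(gsum, gesum) per compartment (nS, pA-contribution).
.steady_terms <- function(cell, v) {
  n <- nrow(cell$comp)
  gsum <- numeric(n); gesum <- numeric(n)
  for (c in seq_along(cell$channels)) {
    sp <- cell$channels[[c]]
    gb <- cell$gbar[, c]
    act <- which(gb > 0)
    if (!length(act)) next
    gv <- gb[act]
    if (sp$p > 0) {
      gv <- gv * steady_state(v[act], sp$activation)^sp$p
      if (!is.null(sp$inactivation))
        gv <- gv * steady_state(v[act], sp$inactivation)
    }
    gsum[act] <- gsum[act] + gv
    gesum[act] <- gesum[act] + gv * sp$e_rev
  }
  list(gsum = gsum, gesum = gesum)
}

# Laplacian part of the current balance: axial currents into each compartment.
.axial_current <- function(cell, v) {
  n <- nrow(cell$comp)
  iax <- numeric(n)
  p <- cell$comp$parent; ga <- cell$comp$g_ax
  for (i in 2:n) {
    d <- ga[i] * (v[p[i]] - v[i])
    iax[i] <- iax[i] + d
    iax[p[i]] <- iax[p[i]] - d
  }
  iax
}

#' Somatic bias current holding the cell at a target potential
#'
#' Solves the full nonlinear cable steady state (all gates at their
#' steady-state values) with the somatic potential clamped to `v_hold`, by
#' Newton iteration on the membrane current balance; the residual somatic
#' current is the holding bias. The solution is then verified by relaxing
#' the model for `verify_ms` under that bias: the somatic potential must
#' stay within 0.1 mV of `v_hold` with no spike, otherwise an error reports
#' that the model is unstable at this holding potential.
#'
#' @param cell a [build_cell()] model.
#' @param v_hold target somatic potential (mV), default -70.
#' @param verify relax-and-check the solution by simulation (default TRUE).
#' @param verify_ms duration of the verification run (ms).
#' @return Bias current (pA), with the full steady state attached as
#'   attribute `"state"` (`v`, `m`, `h` matrices ready for [integrate_cell()]).
#' @export
solve_holding_bias <- function(cell, v_hold = -70, verify = TRUE,
                               verify_ms = 300) {
  n <- nrow(cell$comp)
  v <- rep(v_hold, n)
  free <- 2:n
  for (it in 1:60) {
    st <- .steady_terms(cell, v)
    f <- st$gesum - st$gsum * v + .axial_current(cell, v)
    if (it > 1 && max(abs(f[free])) < 1e-9) break
    # numeric Jacobian over free compartments
    J <- matrix(0, n - 1, n - 1)
    eps <- 1e-4
    for (k in seq_along(free)) {
      vp <- v; vp[free[k]] <- vp[free[k]] + eps
      stp <- .steady_terms(cell, vp)
      fp <- stp$gesum - stp$gsum * vp + .axial_current(cell, vp)
      J[, k] <- (fp[free] - f[free]) / eps
    }
    step <- tryCatch(solve(J, -f[free]), error = function(e)
      stop("solve_holding_bias: singular Jacobian; no stable subthreshold fixed point? Review model parameters."))
    step <- pmax(pmin(step, 15), -15)   # damp
    v[free] <- v[free] + step
    if (max(abs(step)) < 1e-8) break
  }
  st <- .steady_terms(cell, v)
  f <- st$gesum - st$gsum * v + .axial_current(cell, v)
  bias <- -f[1]

  state <- .steady_gate_state(cell, v)

  if (verify) {
    sim <- .run_sim(cell, state, dt = 0.02, n_steps = round(verify_ms / 0.02),
                    i_stim = bias, record = cell$idx$soma)
    vs <- sim$v[, 1]
    if (max(vs) > 0)
      stop("solve_holding_bias: model fires spontaneously at this holding potential; review parameters")
    if (abs(vs[length(vs)] - v_hold) > 0.1)
      stop(sprintf("solve_holding_bias: no stable fixed point at %g mV (relaxed to %.2f); review parameters",
                   v_hold, vs[length(vs)]))
    state$v <- sim$v_final; state$m <- sim$m_final; state$h <- sim$h_final
  }
  structure(bias, state = state)
}

.steady_gate_state <- function(cell, v) {
  n <- nrow(cell$comp); nc <- length(cell$channels)
  m <- matrix(0, n, nc); h <- matrix(1, n, nc)
  for (c in seq_len(nc)) {
    sp <- cell$channels[[c]]
    if (sp$p > 0) m[, c] <- steady_state(v, sp$activation)
    if (!is.null(sp$inactivation)) h[, c] <- steady_state(v, sp$inactivation)
  }
  list(v = v, m = m, h = h)
}

# Low-level wrapper around the compiled integrator.
.run_sim <- function(cell, state, dt, n_steps, i_stim = numeric(0),
                     g_syn = numeric(0), record = NULL,
                     stop_v = NA_real_, stop_after_ms = 3, record_every = 1L) {
  if (is.null(record)) record <- c(cell$idx$soma, cell$idx$ais_mid)
  sim_core(parent = cell$comp$parent - 1L, g_ax = cell$comp$g_ax,
           cm = cell$comp$cm, gbar = cell$gbar, kin = cell$kin,
           v0 = state$v, m0 = state$m, h0 = state$h,
           dt = dt, n_steps = as.integer(n_steps),
           i_stim = as.numeric(i_stim), stim_comp = cell$idx$soma - 1L,
           g_syn = as.numeric(g_syn), syn_comp = cell$idx$soma - 1L,
           e_syn = 0,
           record = as.integer(record - 1L),
           stop_v = stop_v, stop_after_ms = stop_after_ms,
           record_every = as.integer(record_every))
}

# Holding state after the configured settling period (transients discarded).
.settled_state <- function(cell, v_hold = cell$config$simulation$v_hold,
                           settle_ms = cell$config$simulation$settle_ms) {
  bias <- solve_holding_bias(cell, v_hold, verify = FALSE)
  state <- attr(bias, "state")
  if (settle_ms > 0) {
    dt <- max(cell$config$simulation$dt, 0.02)
    sim <- .run_sim(cell, state, dt = dt, n_steps = round(settle_ms / dt),
                    i_stim = as.numeric(bias), record = cell$idx$soma)
    if (!is.null(sim$diverged_at))
      stop("holding-state settling diverged; review model parameters")
    state <- list(v = sim$v_final, m = sim$m_final, h = sim$h_final)
  }
  list(state = state, bias = as.numeric(bias))
}

#' Voltage trace container
#'
#' Uniformly sampled simulated (or synthetic) membrane-potential record with
#' its stimulus channels.
#'
#' @param time time base (ms), uniform.
#' @param v_soma somatic potential (mV).
#' @param v_ais optional AIS mid-point potential (mV).
#' @param i_stim injected command current (pA, excluding holding bias).
#' @param g_syn synaptic conductance command (nS).
#' @param meta named list of provenance fields.
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(time, v_soma, v_ais = NULL, i_stim = NULL,
                          g_syn = NULL, meta = list()) {
  stopifnot(length(time) == length(v_soma))
  dt <- if (length(time) > 1) diff(time[1:2]) else NA_real_
  if (length(time) > 2 && max(abs(diff(time) - dt)) > 1e-9 * max(1, abs(dt)))
    stop("voltage_trace: non-uniform time base")
  structure(list(time = time, dt = dt, t0 = time[1], v_soma = v_soma,
                 v_ais = v_ais,
                 i_stim = if (is.null(i_stim)) rep(0, length(time)) else i_stim,
                 g_syn = if (is.null(g_syn)) rep(0, length(time)) else g_syn,
                 meta = meta),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples, dt = %g ms (%.1f ms), Vm range [%.1f, %.1f] mV\n",
              length(x$time), x$dt, diff(range(x$time)),
              min(x$v_soma), max(x$v_soma)))
  invisible(x)
}

#' @export
as.data.frame.voltage_trace <- function(x, ...) {
  d <- data.frame(time_ms = x$time, v_soma_mV = x$v_soma)
  if (!is.null(x$v_ais)) d$v_ais_mV <- x$v_ais
  d$i_stim_pA <- x$i_stim
  d$g_syn_nS <- x$g_syn
  d
}

#' Integrate the model under a stimulation protocol
#'
#' Starts from the holding steady state at the protocol's holding potential
#' (with the configured settling period discarded), applies the stimulus and
#' returns somatic and AIS mid-point voltage traces. Deterministic.
#'
#' @param cell a [build_cell()] model.
#' @param protocol a single-sweep protocol: either a square step
#'   (`list(kind = "step", amplitude, onset, duration, total_ms, v_hold)`)
#'   or a conductance waveform
#'   (`list(kind = "gsyn", g = <nS vector sampled at dt>, v_hold)`).
#' @param dt integration step (ms), default from the cell config.
#' @param hold optional pre-computed result of the internal holding solver;
#'   used by protocol drivers to avoid re-settling per sweep.
#' @param stop_v,stop_after_ms optional early stop: end the run
#'   `stop_after_ms` after the somatic potential first crosses `stop_v`
#'   upward (NA = integrate the full window).
#' @return A [voltage_trace()].
#' @export
integrate_cell <- function(cell, protocol, dt = cell$config$simulation$dt,
                           hold = NULL, stop_v = NA_real_, stop_after_ms = 3) {
  if (dt <= 0) stop("integrate_cell: dt must be > 0")
  v_hold <- if (!is.null(protocol$v_hold)) protocol$v_hold else
    cell$config$simulation$v_hold
  if (is.null(hold)) hold <- .settled_state(cell, v_hold)

  if (protocol$kind == "step") {
    total <- if (!is.null(protocol$total_ms)) protocol$total_ms else
      protocol$onset + protocol$duration + 20
    n <- round(total / dt)
    tt <- seq_len(n) * dt
    i_cmd <- ifelse(tt > protocol$onset & tt <= protocol$onset + protocol$duration,
                    protocol$amplitude, 0)
    sim <- .run_sim(cell, hold$state, dt, n, i_stim = hold$bias + i_cmd,
                    stop_v = stop_v, stop_after_ms = stop_after_ms)
    nd <- nrow(sim$v)
    tr <- voltage_trace(time = sim$t[seq_len(nd)], v_soma = sim$v[, 1],
                        v_ais = sim$v[, 2], i_stim = c(0, i_cmd)[seq_len(nd)],
                        meta = list(kind = "step", amplitude = protocol$amplitude,
                                    onset = protocol$onset,
                                    duration = protocol$duration,
                                    v_hold = v_hold, bias_pA = hold$bias, dt = dt))
  } else if (protocol$kind == "gsyn") {
    gg <- protocol$g
    n <- length(gg)
    sim <- .run_sim(cell, hold$state, dt, n, i_stim = rep(hold$bias, n),
                    g_syn = gg, stop_v = stop_v, stop_after_ms = stop_after_ms)
    nd <- nrow(sim$v)
    tr <- voltage_trace(time = sim$t[seq_len(nd)], v_soma = sim$v[, 1],
                        v_ais = sim$v[, 2], g_syn = c(0, gg)[seq_len(nd)],
                        meta = list(kind = "gsyn", v_hold = v_hold,
                                    bias_pA = hold$bias, dt = dt))
  } else stop("integrate_cell: unknown protocol kind")

  if (!is.null(sim$diverged_at))
    stop(sprintf("integrate_cell: numerical divergence at t = %.3f ms (dt = %g); reduce dt",
                 sim$diverged_at, dt))
  tr
}
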