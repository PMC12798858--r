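# Stimulation protocols: square current steps, rheobase search, EPSC series.

#' Square-pulse step protocol
#'
#' @param amplitudes step amplitudes (pA), one sweep per value.
#' @param duration step duration (ms); 250 ms is used for threshold
#'   measurements, 500 ms for recording-style protocols.
#' @param v_hold holding potential (mV).
#' @param onset step onset within the sweep (ms).
#' @param tail post-step recording time (ms).
#' @return A list of class `step_protocol`.
#' @export
step_protocol <- function(amplitudes, duration = 250, v_hold = -70,
                          onset = 10, tail = 20) {
  stopifnot(duration > 0, all(is.finite(amplitudes)))
  structure(list(amplitudes = amplitudes, duration = duration,
                 v_hold = v_hold, onset = onset, tail = tail),
            class = "step_protocol")
}

#' EPSC conductance protocol
#'
#' Synaptic conductance transient applied at the soma: dual-exponential
#' waveform with a fixed time to peak and decay time constant, reversal
#' potential 0 mV.
#'
#' @param time_to_peak rise time to the conductance peak (ms), default 0.5.
#' @param decay_tau decay time constant (ms), default 3.
#' @param e_rev synaptic reversal potential (mV), default 0.
#' @param peak_conductances candidate peak conductances (nS), default the
#'   6 to 11 nS series in 0.25 nS steps.
#' @param onset EPSC onset within the sweep (ms).
#' @param v_hold holding potential (mV).
#' @param window_ms simulated window after onset (ms).
#' @return A list of class `epsc_protocol`.
#' @export
epsc_protocol <- function(time_to_peak = 0.5, decay_tau = 3, e_rev = 0,
                          peak_conductances = seq(6, 11, by = 0.25),
                          onset = 5, v_hold = -70, window_ms = 100) {
  stopifnot(time_to_peak > 0, decay_tau > time_to_peak)
  structure(list(time_to_peak = time_to_peak, decay_tau = decay_tau,
                 e_rev = e_rev, peak_conductances = peak_conductances,
                 onset = onset, v_hold = v_hold, window_ms = window_ms),
            class = "epsc_protocol")
}

#' Sampled EPSC conductance waveform
#'
#' Dual-exponential conductance
#' `g(t) = A (exp(-t/tau_decay) - exp(-t/tau_rise))` with the rise constant
#' solved numerically so the peak falls exactly at `time_to_peak`, and `A`
#' normalized so the maximum equals `g_peak`.
#'
#' @param p an [epsc_protocol()].
#' @param g_peak peak conductance (nS).
#' @param dt sample interval (ms); must resolve the rise
#'   (`dt <= time_to_peak`).
#' @param total_ms waveform duration from sweep start (ms).
#' @return Numeric vector of conductances (nS) sampled at
#'   `t = dt, 2 dt, ...`; zero before onset.
#' @export
epsc_conductance_waveform <- function(p, g_peak, dt, total_ms = p$onset + p$window_ms) {
  stopifnot(inherits(p, "epsc_protocol"), g_peak > 0)
  if (dt > p$time_to_peak)
    stop("epsc_conductance_waveform: dt undersamples the rise (dt > time_to_peak)")
  tau_d <- p$decay_tau
  # peak time of the dual exponential: t* = ln(tau_d/tau_r) * tau_d tau_r / (tau_d - tau_r)
  tpk <- function(tau_r) log(tau_d / tau_r) * tau_d * tau_r / (tau_d - tau_r)
  tau_r <- stats::uniroot(function(x) tpk(x) - p$time_to_peak,
                          c(1e-4, tau_d - 1e-6), tol = 1e-12)$root
  tt <- seq_len(round(total_ms / dt)) * dt
  s <- pmax(tt - p$onset, 0)
  w <- exp(-s / tau_d) - exp(-s / tau_r)
  w[tt <= p$onset] <- 0
  peak_val <- exp(-p$time_to_peak / tau_d) - exp(-p$time_to_peak / tau_r)
  g_peak * w / peak_val
}

#' Run a multi-sweep step protocol
#'
#' Each sweep starts from the identical holding steady state.
#'
#' @param cell a [build_cell()] model.
#' @param p a [step_protocol()].
#' @param dt integration step (ms).
#' @return List of [voltage_trace()], one per amplitude.
#' @export
run_step_protocol <- function(cell, p, dt = cell$config$simulation$dt) {
  stopifnot(inherits(p, "step_protocol"))
  hold <- .settled_state(cell, p$v_hold)
  lapply(p$amplitudes, function(a)
    integrate_cell(cell, list(kind = "step", amplitude = a, onset = p$onset,
                              duration = p$duration, v_hold = p$v_hold,
                              total_ms = p$onset + p$duration + p$tail),
                   dt = dt, hold = hold))
}

# one sweep, early-stopped on a spike; returns trace
.step_sweep <- function(cell, hold, amplitude, duration, onset, dt,
                        tail = 5, stop = TRUE) {
  integrate_cell(cell, list(kind = "step", amplitude = amplitude,
                            onset = onset, duration = duration,
                            total_ms = onset + duration + tail),
                 dt = dt, hold = hold,
                 stop_v = if (stop) 0 else NA_real_, stop_after_ms = 3)
}

#' Rheobase by bisection
#'
#' Smallest square-pulse amplitude (to within `resolution`, via bisection
#' between a subthreshold and a suprathreshold bracket) that elicits at
#' least one action potential (10 mV/ms phase-plot criterion) within the
#' step.
#'
#' @param cell a [build_cell()] model.
#' @param duration step duration (ms), default 250.
#' @param resolution bisection resolution (pA), default 1.
#' @param v_hold holding potential (mV).
#' @param bracket_max largest amplitude tried (pA); if no spike at this
#'   amplitude the search fails with "no rheobase found".
#' @param dt integration step (ms).
#' @param criterion threshold detection criterion (mV/ms).
#' @param hold optional pre-computed holding state (internal use).
#' @return Rheobase (pA), with attributes `trace` (the suprathreshold sweep
#'   at the returned amplitude, early-stopped shortly after the spike peak)
#'   and `n_sim` (number of sweeps integrated).
#' @export
find_rheobase <- function(cell, duration = 250, resolution = 1, v_hold = -70,
                          bracket_max = 1000, dt = cell$config$simulation$dt,
                          criterion = 10, hold = NULL) {
  stopifnot(resolution > 0)
  if (is.null(hold)) hold <- .settled_state(cell, v_hold)
  onset <- 5
  n_sim <- 0L
  spikes <- function(amp) {
    tr <- .step_sweep(cell, hold, amp, duration, onset, dt)
    n_sim <<- n_sim + 1L
    list(n = nrow(detect_aps(tr, criterion = criterion)), trace = tr)
  }
  lo <- 0; hi <- 100
  hit <- NULL
  repeat {
    r <- spikes(hi)
    if (r$n > 0) { hit <- r$trace; break }
    lo <- hi
    hi <- hi * 2
    if (hi > bracket_max) {
      r <- spikes(bracket_max)
      if (r$n > 0) { hi <- bracket_max; hit <- r$trace; break }
      stop("find_rheobase: no rheobase found (no AP up to bracket maximum)")
    }
  }
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    r <- spikes(mid)
    if (r$n > 0) { hi <- mid; hit <- r$trace } else lo <- mid
  }
  structure(hi, trace = hit, n_sim = n_sim)
}

#' Threshold EPSC conductance and AP generation lag
#'
#' Applies the EPSC series in ascending order of peak conductance and
#' returns the smallest listed conductance that elicits an AP (10 mV/ms
#' criterion), together with the EPSC-onset-to-AP-onset lag for every
#' suprathreshold conductance.
#'
#' @param cell a [build_cell()] model.
#' @param p an [epsc_protocol()]; `peak_conductances` must be ascending.
#' @param dt integration step (ms).
#' @param criterion threshold criterion (mV/ms).
#' @param hold optional pre-computed holding state (internal use).
#' @return List of class `epsc_threshold`: `g_threshold` (nS, NA if none
#'   suprathreshold), `lags` (data.frame `g_peak_nS`, `spike`, `lag_ms`,
#'   `v_threshold_mV`).
#' @export
find_threshold_epsc <- function(cell, p = epsc_protocol(),
                                dt = cell$config$simulation$dt,
                                criterion = 10, hold = NULL) {
  stopifnot(inherits(p, "epsc_protocol"))
  gs <- p$peak_conductances
  if (is.unsorted(gs)) stop("find_threshold_epsc: peak_conductances must be ascending")
  if (is.null(hold)) hold <- .settled_state(cell, p$v_hold)
  rows <- lapply(gs, function(g) {
    r <- epsc_response(cell, p, g, dt = dt, criterion = criterion, hold = hold)
    data.frame(g_peak_nS = g, spike = r$spike, lag_ms = r$lag_ms,
               v_threshold_mV = r$v_threshold_mV)
  })
  lags <- do.call(rbind, rows)
  g_thr <- if (any(lags$spike)) min(lags$g_peak_nS[lags$spike]) else NA_real_
  structure(list(g_threshold = g_thr, lags = lags), class = "epsc_threshold")
}

#' Single EPSC response
#'
#' Applies one somatic EPSC and reports whether it triggered an AP, the
#' EPSC-onset-to-AP-onset lag and the threshold potential.
#'
#' @inheritParams find_threshold_epsc
#' @param g_peak peak conductance (nS).
#' @return List: `spike` (logical), `lag_ms`, `v_threshold_mV`, `trace`.
#' @export
epsc_response <- function(cell, p, g_peak, dt = cell$config$simulation$dt,
                          criterion = 10, hold = NULL) {
  if (is.null(hold)) hold <- .settled_state(cell, p$v_hold)
  gg <- epsc_conductance_waveform(p, g_peak, dt)
  tr <- integrate_cell(cell, list(kind = "gsyn", g = gg, v_hold = p$v_hold),
                       dt = dt, hold = hold, stop_v = 0, stop_after_ms = 3)
  aps <- detect_aps(tr, criterion = criterion)
  if (nrow(aps) == 0)
    return(list(spike = FALSE, lag_ms = NA_real_, v_threshold_mV = NA_real_,
                trace = tr))
  list(spike = TRUE, lag_ms = aps$t_threshold[1] - p$onset,
       v_threshold_mV = aps$v_threshold[1], trace = tr)
}

#' @export
print.epsc_threshold <- function(x, ...) {
  cat(sprintf("<epsc_threshold> g_threshold = %s nS; %d/%d conductances suprathreshold\n",
              format(x$g_threshold), sum(x$lags$spike), nrow(x$lags)))
  invisible(x)
}
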