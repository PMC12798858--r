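# Electrophysiological feature definitions: phase plot, AP detection with the
# 10 mV/ms threshold criterion, per-AP waveform features and passive
# properties (Rin, apparent tau).

#' Phase plot of a voltage trace
#'
#' First derivative of the somatic potential against the potential itself.
#' dV/dt is estimated by central differences; no smoothing is applied by
#' default. An optional 3-point running-median prefilter is available for
#' noisy recorded/synthetic traces.
#'
#' @param trace a [voltage_trace()].
#' @param prefilter apply a 3-point median prefilter to Vm first.
#' @return data.frame with columns `t`, `v` (mV) and `dvdt` (mV/ms), one row
#'   per interior sample (boundary samples dropped).
#' @export
phase_plot <- function(trace, prefilter = FALSE) {
  stopifnot(inherits(trace, "voltage_trace"))
  v <- trace$v_soma
  n <- length(v)
  if (n < 3) stop("phase_plot: trace shorter than 3 samples")
  if (prefilter) v <- stats::runmed(v, 3)
  dvdt <- (v[3:n] - v[1:(n - 2)]) / (2 * trace$dt)
  data.frame(t = trace$time[2:(n - 1)], v = v[2:(n - 1)], dvdt = dvdt)
}

#' Detect action potentials with the phase-plot threshold criterion
#'
#' An AP is the first upward crossing of `dV/dt >= criterion` followed by a
#' membrane-potential maximum exceeding the spike-validation level, then the
#' post-peak trough. The threshold is the potential at the criterion
#' crossing, linearly interpolated between the bracketing samples.
#'
#' @param trace a [voltage_trace()].
#' @param criterion rise-speed criterion (mV/ms), default 10.
#' @param min_peak spike-validation level (mV): events whose peak stays below
#'   this are not counted as APs (default -10).
#' @param interpolate linearly interpolate the threshold crossing (default
#'   TRUE; FALSE returns the first supra-criterion sample).
#' @param prefilter 3-point median prefilter for noisy traces.
#' @return data.frame with one row per detected AP: `t_threshold`,
#'   `v_threshold`, `t_peak`, `v_peak`, `t_trough`, `v_trough` (NA when the
#'   trough is truncated), and sample indices `i_start`, `i_peak`, `i_end`
#'   delimiting the AP window in the trace. Zero rows when no AP.
#' @export
detect_aps <- function(trace, criterion = 10, min_peak = -10,
                       interpolate = TRUE, prefilter = FALSE) {
  stopifnot(criterion > 0)
  pp <- phase_plot(trace, prefilter = prefilter)
  v <- pp$v; dvdt <- pp$dvdt; tt <- pp$t
  n <- length(v)
  out <- list()
  dt <- trace$dt
  peak_window <- max(3L, round(10 / dt))  # peak must follow within 10 ms
  i <- 2
  while (i <= n) {
    if (dvdt[i] >= criterion && dvdt[i - 1] < criterion) {
      # candidate episode; Vm maximum: running max until Vm falls clearly
      # (10 mV) below it, robust to sample-level derivative noise
      j <- i; i_peak <- i; vmax <- v[i]
      while (j < n && j - i <= peak_window) {
        j <- j + 1
        if (v[j] > vmax) { vmax <- v[j]; i_peak <- j }
        if (vmax - v[j] > 10) break
      }
      # AP onset: the last upward criterion crossing before the peak (the
      # upstroke's own crossing, not e.g. a stimulus-onset transient)
      io <- i_peak
      while (io > 2 && !(dvdt[io] >= criterion && dvdt[io - 1] < criterion))
        io <- io - 1
      # spike validation: the peak must clear the validation level AND the
      # rise must accelerate beyond the criterion after the crossing -- a
      # monotonically decelerating depolarization (e.g. passive charging
      # toward a high plateau) is not an AP
      imax <- which.max(dvdt[io:i_peak]) + io - 1
      # (io + 1 exclusion: a square stimulus edge spreads over two samples
      # under central differencing)
      accelerates <- imax > io + 1 || max(dvdt[io:i_peak]) >= 5 * criterion
      if (v[i_peak] > min_peak && accelerates) {
        # trough: running minimum after the peak until Vm recovers 5 mV
        k <- i_peak; i_tr <- i_peak; vmin <- v[i_peak]
        while (k < n) {
          k <- k + 1
          if (v[k] < vmin) { vmin <- v[k]; i_tr <- k }
          if (v[k] - vmin > 5) break
        }
        truncated <- k >= n && (v[n] - vmin <= 5)
        if (interpolate) {
          f <- (criterion - dvdt[io - 1]) / (dvdt[io] - dvdt[io - 1])
          v_thr <- v[io - 1] + f * (v[io] - v[io - 1])
          t_thr <- tt[io - 1] + f * (tt[io] - tt[io - 1])
        } else { v_thr <- v[io]; t_thr <- tt[io] }
        out[[length(out) + 1]] <- data.frame(
          t_threshold = t_thr, v_threshold = v_thr,
          t_peak = tt[i_peak], v_peak = v[i_peak],
          t_trough = if (truncated) NA_real_ else tt[i_tr],
          v_trough = if (truncated) NA_real_ else v[i_tr],
          i_start = io, i_peak = i_peak, i_end = min(k, n))
        i <- k + 1
        next
      }
      # not a spike: skip past this supra-criterion episode
      while (i < n && dvdt[i] >= criterion) i <- i + 1
    }
    i <- i + 1
  }
  if (!length(out))
    return(data.frame(t_threshold = numeric(0), v_threshold = numeric(0),
                      t_peak = numeric(0), v_peak = numeric(0),
                      t_trough = numeric(0), v_trough = numeric(0),
                      i_start = integer(0), i_peak = integer(0),
                      i_end = integer(0)))
  do.call(rbind, out)
}

#' Waveform features of a single action potential
#'
#' Computes the feature vector used for AP characterization:
#' half-width (time between the two crossings of the level midway between
#' threshold and peak), AHP amplitude (trough minus threshold, negative
#' going; missing when no trough below threshold is contained in the
#' window), maximal rise and fall speed (phase-plot extrema), and the
#' initial rise slope (maximum slope d(dV/dt)/dV of the phase plot above
#' the criterion point and below the phase-plot peak, in 1/ms).
#'
#' @param trace a [voltage_trace()].
#' @param ap one row of the [detect_aps()] table.
#' @param criterion the detection criterion used (mV/ms).
#' @return data.frame (one row): `threshold`, `peak`, `half_width`,
#'   `ahp_amplitude`, `max_rise`, `max_fall`, `initial_rise_slope`.
#'   Unmeasurable features are NA, never fabricated.
#' @export
ap_features <- function(trace, ap, criterion = 10) {
  pp <- phase_plot(trace)
  win <- ap$i_start:ap$i_end
  v <- pp$v[win]; dvdt <- pp$dvdt[win]; tt <- pp$t[win]

  half_level <- ap$v_threshold + 0.5 * (ap$v_peak - ap$v_threshold)
  cross <- function(seg_v, seg_t) {
    idx <- which(diff(sign(seg_v - half_level)) != 0)
    if (!length(idx)) return(NA_real_)
    i <- idx[1]
    seg_t[i] + (half_level - seg_v[i]) / (seg_v[i + 1] - seg_v[i]) *
      (seg_t[i + 1] - seg_t[i])
  }
  ip <- ap$i_peak - ap$i_start + 1
  t_up <- cross(v[1:ip], tt[1:ip])
  t_down <- if (ip < length(v)) cross(v[ip:length(v)], tt[ip:length(v)]) else NA_real_
  half_width <- t_down - t_up

  ahp <- if (is.na(ap$v_trough) || ap$v_trough >= ap$v_threshold) NA_real_
         else ap$v_trough - ap$v_threshold

  # initial rise slope: steepest phase-plot segment on the rising limb,
  # above the criterion point and below the dV/dt maximum
  rise <- 1:ip
  sel <- rise[dvdt[rise] >= criterion & dvdt[rise] < max(dvdt[rise])]
  irs <- if (length(sel) >= 2) {
    dv <- diff(v[sel]); ok <- abs(dv) > 1e-12
    if (any(ok)) max(diff(dvdt[sel])[ok] / dv[ok]) else NA_real_
  } else NA_real_

  data.frame(threshold = ap$v_threshold, peak = ap$v_peak,
             half_width = half_width, ahp_amplitude = ahp,
             max_rise = max(dvdt), max_fall = min(dvdt),
             initial_rise_slope = irs)
}

#' AP latency and spike count in a step sweep
#'
#' @param trace a [voltage_trace()] from a step protocol.
#' @param step_onset step onset time (ms); taken from the trace's stimulus
#'   channel when omitted.
#' @param criterion threshold criterion (mV/ms).
#' @return list(`latency` = first threshold crossing minus onset (ms; NA if
#'   no AP), `spike_count` = number of validated APs).
#' @export
latency_and_count <- function(trace, step_onset = NULL, criterion = 10) {
  if (is.null(step_onset)) {
    on <- which(trace$i_stim != 0)
    if (!length(on)) stop("latency_and_count: no stimulus in trace; give step_onset")
    step_onset <- trace$time[on[1]]
  }
  aps <- detect_aps(trace, criterion = criterion)
  if (nrow(aps) == 0) return(list(latency = NA_real_, spike_count = 0L))
  list(latency = aps$t_threshold[1] - step_onset, spike_count = nrow(aps))
}

#' Input resistance from subthreshold steps
#'
#' Rin is the mean over sweeps of the steady-state voltage deflection per
#' injected current; the steady-state deflection is read from the final 20%
#' of the step. Sweeps containing an AP are excluded with a warning; if all
#' sweeps are excluded, an error is raised.
#'
#' @param traces list of [voltage_trace()] from subthreshold steps (the step
#'   window and amplitude are read from each trace's stimulus channel).
#' @return Rin (Mohm), attribute `"per_sweep"` with the per-sweep values.
#' @export
measure_rin <- function(traces) {
  if (inherits(traces, "voltage_trace")) traces <- list(traces)
  vals <- vapply(traces, function(tr) {
    on <- which(tr$i_stim != 0)
    if (!length(on)) return(NA_real_)
    amp <- tr$i_stim[on[1]]
    if (nrow(detect_aps(tr)) > 0) {
      warning("measure_rin: sweep with AP excluded")
      return(NA_real_)
    }
    i0 <- on[1]; i1 <- on[length(on)]
    tail_idx <- i0 + seq(floor(0.8 * (i1 - i0)), i1 - i0)
    v_base <- mean(tr$v_soma[1:(i0 - 1)])
    dv <- mean(tr$v_soma[tail_idx]) - v_base
    dv / amp * 1000  # mV/pA -> Mohm
  }, numeric(1))
  if (all(is.na(vals))) stop("measure_rin: all sweeps excluded or unstimulated")
  structure(mean(vals, na.rm = TRUE), per_sweep = vals)
}

#' Apparent membrane time constant from a subthreshold step
#'
#' Single-exponential least-squares fit
#' `V(t) = V_ss - dV * exp(-(t - onset)/tau)` to the ascending phase of the
#' step response, over a window from the onset to five times an initial tau
#' guess (the 63% rise time).
#'
#' @param trace a subthreshold [voltage_trace()] step response.
#' @return tau (ms) with attribute `"fit"` (the `nls` object).
#' @export
measure_tau <- function(trace) {
  on <- which(trace$i_stim != 0)
  if (!length(on)) stop("measure_tau: no stimulus in trace")
  if (nrow(detect_aps(trace)) > 0) stop("measure_tau: trace contains an AP")
  i0 <- on[1]; i1 <- on[length(on)]
  t_on <- trace$time[i0]
  v_base <- mean(trace$v_soma[1:(i0 - 1)])
  v_ss <- mean(trace$v_soma[(i0 + floor(0.8 * (i1 - i0))):i1])
  dv <- v_ss - v_base
  # initial guess: 63% rise time
  i63 <- which(abs(trace$v_soma[i0:i1] - v_base) >= 0.632 * abs(dv))[1]
  tau0 <- max(trace$dt, trace$time[i0 + i63 - 1] - t_on)
  iw <- which(trace$time > t_on & trace$time <= min(t_on + 5 * tau0, trace$time[i1]))
  d <- data.frame(t = trace$time[iw] - t_on, v = trace$v_soma[iw])
  fit <- tryCatch(
    stats::nls(v ~ vss - dvv * exp(-t / tau), data = d,
               start = list(vss = v_ss, dvv = dv, tau = tau0),
               # scaleOffset keeps the convergence test defined for
               # zero-residual (noiseless synthetic) data
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE,
                                            scaleOffset = 1)),
    error = function(e)
      stop(sprintf("measure_tau: exponential fit failed (%s); residual sd of linear baseline %.3g mV",
                   conditionMessage(e), stats::sd(d$v))))
  structure(unname(coef(fit)["tau"]), fit = fit)
}

#' Per-trace feature table
#'
#' Convenience wrapper combining AP detection, first-AP waveform features
#' and latency/count into one row per trace.
#'
#' @param trace a [voltage_trace()].
#' @param criterion threshold criterion (mV/ms).
#' @param prefilter 3-point median prefilter for noisy traces.
#' @return One-row data.frame: threshold, peak, half_width, ahp_amplitude,
#'   max_rise, max_fall, initial_rise_slope, latency, spike_count. NA where
#'   not measurable.
#' @export
trace_features <- function(trace, criterion = 10, prefilter = FALSE) {
  aps <- detect_aps(trace, criterion = criterion, prefilter = prefilter)
  if (nrow(aps) == 0)
    return(data.frame(threshold = NA_real_, peak = NA_real_,
                      half_width = NA_real_, ahp_amplitude = NA_real_,
                      max_rise = NA_real_, max_fall = NA_real_,
                      initial_rise_slope = NA_real_, latency = NA_real_,
                      spike_count = 0L))
  fx <- ap_features(trace, aps[1, ], criterion = criterion)
  lc <- tryCatch(latency_and_count(trace, criterion = criterion),
                 error = function(e) list(latency = NA_real_,
                                          spike_count = nrow(aps)))
  cbind(fx, latency = lc$latency, spike_count = lc$spike_count)
}
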