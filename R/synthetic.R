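# Synthetic voltage traces and feature cohorts with exact ground truth.
#
# The AP template is a sum of logistic (sigmoid) components whose closed form
# is differentiable analytically, so the 10 mV/ms crossing used as the
# detector's ground truth is solved from the template's exact derivative
# (root-finding on the closed form, not on sampled data).

# run expr with a local, seeded RNG; restores global state afterwards
.with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("synthetic generators require an explicit seed")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of one synthetic cell / AP template
#'
#' @param threshold programmed AP threshold: the membrane potential at which
#'   the template's rise speed crosses 10 mV/ms (mV).
#' @param peak programmed AP peak (mV).
#' @param ahp_depth AHP trough below threshold (mV, positive number).
#' @param rise_w,fall_w upstroke/downstroke logistic widths (ms).
#' @param ahp_tau recovery time constant from the AHP trough (ms).
#' @param baseline holding potential (mV).
#' @param charge_tau membrane charging time constant toward the plateau (ms).
#' @param plateau_dv plateau depolarization above baseline during the step
#'   (mV); the AP rides on this plateau.
#' @param rin,tau passive properties used by passive-trace generation (Mohm,
#'   ms).
#' @param noise_sd additive Gaussian noise (mV).
#' @param seed RNG seed; mandatory for any stochastic call.
#' @return list of class `synthetic_cell_spec`.
#' @export
synthetic_cell_spec <- function(threshold = -38.9, peak = 15.6,
                                ahp_depth = 19.7, rise_w = 0.12,
                                fall_w = 0.18, ahp_tau = 8,
                                baseline = -70, charge_tau = 5,
                                plateau_dv = NULL, rin = 187.9, tau = 6.65,
                                noise_sd = 0, seed = NULL) {
  if (peak <= threshold) stop("synthetic_cell_spec: peak must exceed threshold")
  if (noise_sd < 0) stop("synthetic_cell_spec: noise_sd must be >= 0")
  if (is.null(plateau_dv)) plateau_dv <- (threshold - baseline) * 0.85
  structure(list(threshold = threshold, peak = peak, ahp_depth = ahp_depth,
                 rise_w = rise_w, fall_w = fall_w, ahp_tau = ahp_tau,
                 baseline = baseline, charge_tau = charge_tau,
                 plateau_dv = plateau_dv, rin = rin, tau = tau,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_cell_spec")
}

# Closed-form AP template (single AP, origin t = 0 at the upstroke midpoint)
# and its exact time derivative. Returns functions v(t), dv(t).
# A1/w1 are the (calibrated) upstroke amplitude and logistic width.
.ap_template <- function(spec, v_base, A1, w1) {
  trough <- spec$threshold - spec$ahp_depth
  A2 <- v_base + A1 - trough
  w2 <- spec$fall_w
  t2 <- 6 * w1 + 4 * w2          # downstroke midpoint after the peak region
  A3 <- v_base - trough           # recovery back to the plateau/baseline
  t3 <- t2 + 6 * w2
  lg <- function(x) 1 / (1 + exp(-x))
  v <- function(t)
    v_base + A1 * lg(t / w1) - A2 * lg((t - t2) / w2) +
      A3 * (t > t3) * (1 - exp(-(pmax(t - t3, 0)) / spec$ahp_tau))
  dv <- function(t) {
    s1 <- lg(t / w1); s2 <- lg((t - t2) / w2)
    A1 * s1 * (1 - s1) / w1 - A2 * s2 * (1 - s2) / w2 +
      A3 * (t > t3) * exp(-(pmax(t - t3, 0)) / spec$ahp_tau) / spec$ahp_tau
  }
  list(v = v, dv = dv, t2 = t2, t3 = t3)
}

# Exact 10 mV/ms upstroke crossing of a closed-form waveform vfun/dvfun
# around the upstroke (search window given); returns c(t, v). Brackets the
# last upward crossing below `upper` on a fine grid, then polishes by
# root-finding on the closed form.
.exact_crossing <- function(vfun, dvfun, lower, upper, criterion = 10) {
  g <- seq(lower, upper, length.out = 4000)
  f <- dvfun(g) - criterion
  up <- which(f[-1] >= 0 & f[-length(f)] < 0)
  if (!length(up)) stop("no criterion crossing in the search window")
  i <- up[length(up)]
  r <- stats::uniroot(function(t) dvfun(t) - criterion, c(g[i], g[i + 1]),
                      tol = 1e-13)
  c(t = r$root, v = vfun(r$root))
}

#' Synthetic AP train trace with exact ground-truth annotations
#'
#' Generates a piecewise-smooth template: exponential charging from baseline
#' toward a subthreshold plateau after step onset, plus logistic-upstroke AP
#' waveforms at the programmed spike times, with optional seeded Gaussian
#' noise. The upstroke width is calibrated by fixed-point iteration so the
#' noiseless template's exact 10 mV/ms crossing occurs at the programmed
#' threshold potential; annotations carry the exact crossing values computed
#' from the closed form.
#'
#' @param spec a [synthetic_cell_spec()].
#' @param dt sample interval (ms); must be at most half the calibrated
#'   upstroke width so the crossing is unambiguous at the sampling rate.
#' @param n_aps number of APs.
#' @param onset step onset (ms).
#' @param first_ap_latency latency from onset to the first programmed
#'   threshold crossing (ms).
#' @param isi inter-spike interval (ms).
#' @param total_ms trace duration (ms).
#' @return A [voltage_trace()] whose `meta$ground_truth` holds the exact
#'   per-AP threshold crossings (`t`, `v`), peak, trough, and the generator
#'   spec; `meta$onset` is the step onset.
#' @export
synth_ap_trace <- function(spec, dt = 0.01, n_aps = 1, onset = 10,
                           first_ap_latency = 19.6, isi = 15,
                           total_ms = NULL) {
  stopifnot(inherits(spec, "synthetic_cell_spec"))
  if (is.null(total_ms))
    total_ms <- onset + first_ap_latency + (n_aps - 1) * isi + 40

  v_plateau <- spec$baseline + spec$plateau_dv
  charge_v <- function(t) spec$baseline +
    spec$plateau_dv * (t > onset) * (1 - exp(-pmax(t - onset, 0) / spec$charge_tau))
  charge_dv <- function(t)
    spec$plateau_dv * (t > onset) * exp(-pmax(t - onset, 0) / spec$charge_tau) /
      spec$charge_tau

  # --- calibrate the upstroke so the exact 10 mV/ms crossing of the closed
  # form sits at the programmed threshold, and the waveform maximum at the
  # programmed peak. The crossing potential is translation-invariant, so it
  # is pinned by the logistic WIDTH w1 (solved by root-finding); the peak is
  # pinned by the amplitude A1 (fixed-point); midpoints then set the timing.
  gt <- vector("list", n_aps)
  w1 <- spec$rise_w
  if (n_aps > 0) {
    if (spec$threshold <= v_plateau + 0.5)
      stop("synth_ap_trace: threshold must lie above the subthreshold plateau")
    t_want <- onset + first_ap_latency + (seq_len(n_aps) - 1) * isi
    A1 <- spec$peak - v_plateau
    mids <- t_want + 1
    mk_funs <- function(A1, w1, mids) {
      tmpl <- .ap_template(spec, v_plateau, A1, w1)
      vfun <- function(t) {
        out <- charge_v(t)
        for (mk in mids) out <- out + (tmpl$v(t - mk) - v_plateau)
        out
      }
      dvfun <- function(t) {
        out <- charge_dv(t)
        for (mk in mids) out <- out + tmpl$dv(t - mk)
        out
      }
      list(v = vfun, dv = dvfun, t2 = tmpl$t2)
    }
    s_star <- (spec$threshold - v_plateau) / (spec$peak - v_plateau)
    mids <- t_want + 1
    for (iter in 1:60) {
      s_star <- (spec$threshold - v_plateau) / A1
      if (s_star >= 0.45)
        stop("synth_ap_trace: threshold too close to peak for a logistic upstroke")
      # width solving the single-logistic crossing; exactness restored below
      w1_lo <- A1 * s_star * (1 - s_star) / 10
      # crossing V of the full form as a function of w1 (first AP, current mids)
      cross_v <- function(w1c) {
        f <- mk_funs(A1, w1c, mids)
        .exact_crossing(f$v, f$dv, mids[1] - 14 * w1c, mids[1])["v"]
      }
      w1 <- tryCatch(
        stats::uniroot(function(w) cross_v(w) - spec$threshold,
                       c(w1_lo * 0.5, w1_lo * 1.5), extendInt = "yes",
                       tol = 1e-13)$root,
        error = function(e) w1_lo)
      f <- mk_funs(A1, w1, mids)
      # align timing: first crossing exactly at t_want
      cr <- .exact_crossing(f$v, f$dv, mids[1] - 14 * w1, mids[1])
      mids <- mids + (t_want[1] - cr["t"])
      f <- mk_funs(A1, w1, mids)
      cr <- .exact_crossing(f$v, f$dv, mids[1] - 14 * w1, mids[1])
      # actual maximum (continuous optimization on the closed form)
      opt <- stats::optimize(f$v, c(mids[1], mids[1] + f$t2),
                             maximum = TRUE, tol = 1e-12)
      pk_err <- spec$peak - opt$objective
      th_err <- spec$threshold - cr["v"]
      t_err <- t_want[1] - cr["t"]
      if (abs(pk_err) < 1e-9 && abs(th_err) < 1e-9 && abs(t_err) < 1e-9) break
      A1 <- A1 + pk_err
    }
    f <- mk_funs(A1, w1, mids)
    vfun <- f$v
    for (k in seq_len(n_aps)) {
      cr <- .exact_crossing(f$v, f$dv, mids[k] - 12 * w1, mids[k])
      opt <- stats::optimize(f$v, c(mids[k], mids[k] + f$t2),
                             maximum = TRUE, tol = 1e-10)
      gt[[k]] <- list(t = unname(cr["t"]), v = unname(cr["v"]),
                      t_peak = opt$maximum, v_peak = opt$objective)
    }
  } else {
    vfun <- charge_v
  }

  if (n_aps > 0 && dt > w1 / 2)
    stop(sprintf("synth_ap_trace: dt too coarse to realize the 10 mV/ms crossing unambiguously (upstroke width %.3g ms)", w1))

  tt <- seq(0, total_ms, by = dt)
  vm <- vfun(tt)
  if (spec$noise_sd > 0)
    vm <- vm + .with_seed(spec$seed, rnorm(length(vm), 0, spec$noise_sd))
  i_stim <- ifelse(tt > onset, 1, 0) * spec$plateau_dv / spec$rin * 1000

  voltage_trace(tt, vm, i_stim = i_stim,
                meta = list(kind = "synthetic_ap", onset = onset,
                            ground_truth = gt, spec = spec))
}

#' Synthetic passive charging trace
#'
#' Exact single-exponential charging response
#' `V(t) = V0 + Rin * I * (1 - exp(-(t-onset)/tau))` with seeded additive
#' Gaussian noise.
#'
#' @param rin input resistance (Mohm).
#' @param tau membrane time constant (ms).
#' @param step_pA step amplitude (pA).
#' @param noise_sd Gaussian noise sd (mV).
#' @param seed RNG seed (mandatory when `noise_sd > 0`).
#' @param dt sample interval (ms).
#' @param onset,duration,total_ms step timing (ms).
#' @param v0 baseline potential (mV).
#' @return A [voltage_trace()]; `meta$ground_truth` holds rin and tau.
#' @export
synth_passive_trace <- function(rin, tau, step_pA = 50, noise_sd = 0,
                                seed = NULL, dt = 0.05, onset = 10,
                                duration = 150, total_ms = onset + duration + 40,
                                v0 = -70) {
  stopifnot(rin > 0, tau > 0)
  tt <- seq(0, total_ms, by = dt)
  dv_ss <- rin * step_pA / 1000
  s <- pmax(tt - onset, 0)
  vm <- v0 + dv_ss * (tt > onset) * (1 - exp(-s / tau))
  off <- onset + duration
  dec <- tt > off
  vm[dec] <- v0 + (dv_ss * (1 - exp(-duration / tau))) *
    exp(-(tt[dec] - off) / tau)
  if (noise_sd > 0) vm <- vm + .with_seed(seed, rnorm(length(vm), 0, noise_sd))
  i_stim <- ifelse(tt > onset & tt <= off, step_pA, 0)
  voltage_trace(tt, vm, i_stim = i_stim,
                meta = list(kind = "synthetic_passive",
                            ground_truth = list(rin = rin, tau = tau)))
}

# Fit a shifted log-normal (or mirrored, or normal) to (q1, median, q3).
.quantile_family <- function(q1, med, q3) {
  a <- stats::qnorm(0.75)
  up <- q3 - med; lo <- med - q1
  if (up <= 0 || lo <= 0) stop("quantile triple must be strictly ordered")
  r <- up / lo
  if (abs(log(r)) < 1e-6) {
    sd <- up / a
    return(function(n) stats::rnorm(n, med, sd))
  }
  mirror <- r < 1
  if (mirror) { r <- 1 / r; tmp <- up; up <- lo; lo <- tmp }
  sigma <- log(r) / a
  e_mu <- lo / (1 - exp(-a * sigma))
  shift <- med - e_mu
  if (mirror)
    function(n) 2 * med - (shift + stats::rlnorm(n, log(e_mu), sigma))
  else
    function(n) shift + stats::rlnorm(n, log(e_mu), sigma)
}

#' Reference AP/passive feature targets
#'
#' Bundled median and interquartile targets for cortical fast-spiking
#' (parvalbumin) interneuron AP and passive-membrane features in human and
#' mouse, used as the default parameterization of [synth_cohort()].
#'
#' @param species "human" or "mouse".
#' @return data.frame with columns `feature`, `median`, `q1`, `q3`.
#' @export
cohort_targets <- function(species = c("human", "mouse")) {
  species <- match.arg(species)
  h <- data.frame(
    feature = c("threshold", "initial_rise_slope", "peak", "half_width",
                "rheobase", "latency", "spike_count", "ahp_amplitude",
                "max_rise", "max_fall", "rin", "tau"),
    median = c(-38.9, 30.9, 15.6, 0.496, 87.4, 19.6, 3.8, -19.7, 246.9,
               -122.8, 187.9, 6.65),
    q1 = c(-42.8, 23.8, 9.08, 0.407, 47.5, 12.6, 1.8, -23.6, 170.5, -165.0,
           103.8, 4.22),
    q3 = c(-34.2, 35.5, 25.0, 0.676, 140.0, 33.7, 11.8, -16.2, 335.9, -82.7,
           279.8, 8.17))
  m <- data.frame(
    feature = h$feature,
    median = c(-32.5, 33.2, 15.9, 0.362, 247.6, 50.5, 5.0, -18.6, 255.3,
               -153.7, 125.7, 4.17),
    q1 = c(-35.9, 28.9, 8.2, 0.320, 142.2, 17.9, 2.5, -21.1, 202.1, -213.9,
           89.5, 3.27),
    q3 = c(-28.3, 39.0, 23.5, 0.416, 418.4, 79.9, 8.0, -15.9, 320.7, -113.7,
           167.5, 6.12))
  if (species == "human") h else m
}

#' Synthetic per-cell feature cohort
#'
#' Draws per-cell feature vectors from quantile-matched shifted log-normal
#' distributions (mirrored for left-skewed features; normal when the
#' quartiles are symmetric) whose median and quartiles match the requested
#' targets. The default targets are the bundled human reference values
#' ([cohort_targets()]).
#'
#' @param n number of cells.
#' @param targets data.frame with columns `feature`, `median`, `q1`, `q3`.
#' @param seed RNG seed (mandatory).
#' @return data.frame, one row per cell, one column per feature (plus
#'   `cell_id`), schema-compatible with the feature-extraction output.
#' @export
synth_cohort <- function(n, targets = cohort_targets("human"), seed) {
  stopifnot(n >= 1, all(c("feature", "median", "q1", "q3") %in% names(targets)))
  bad <- with(targets, q1 >= median | median >= q3)
  if (any(bad))
    stop(sprintf("synth_cohort: unordered quantile triple for: %s",
                 paste(targets$feature[bad], collapse = ", ")))
  .with_seed(seed, {
    cols <- lapply(seq_len(nrow(targets)), function(i)
      .quantile_family(targets$q1[i], targets$median[i], targets$q3[i])(n))
    names(cols) <- targets$feature
    cbind(data.frame(cell_id = seq_len(n)), as.data.frame(cols))
  })
}
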