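# Baseline calibration and AIS parameter-sweep experiments.

#' Measure the AP firing threshold of a model cell
#'
#' Standard threshold measurement used throughout the sweep experiments:
#' find the rheobase of a 250-ms square pulse by bisection (1 pA
#' resolution), then read the threshold (10 mV/ms phase-plot criterion,
#' linear interpolation) from the first AP of a just-suprathreshold sweep
#' at `rheobase + margin`. The small fixed margin keeps the readout off the
#' divergent-latency edge at exact rheobase, where the criterion crossing
#' is numerically ill-conditioned.
#'
#' @param cell a [build_cell()] model.
#' @param duration step duration (ms), default 250.
#' @param margin suprathreshold readout margin above rheobase (pA).
#' @param resolution rheobase bisection resolution (pA).
#' @param v_hold holding potential (mV).
#' @param dt integration step (ms).
#' @param hold optional pre-computed holding state (internal use).
#' @return Threshold (mV) with attributes `rheobase` (pA) and `trace`.
#' @export
measure_threshold <- function(cell, duration = 250, margin = 2,
                              resolution = 1, v_hold = -70,
                              dt = cell$config$simulation$dt, hold = NULL) {
  if (is.null(hold)) hold <- .settled_state(cell, v_hold)
  rh <- find_rheobase(cell, duration = duration, resolution = resolution,
                      v_hold = v_hold, dt = dt, hold = hold)
  tr <- .step_sweep(cell, hold, as.numeric(rh) + margin, duration, 5, dt)
  aps <- detect_aps(tr)
  if (nrow(aps) == 0)
    stop("measure_threshold: no AP in the suprathreshold readout sweep")
  structure(aps$v_threshold[1], rheobase = as.numeric(rh), trace = tr)
}

#' Calibrate the baseline model to target response properties
#'
#' Deterministic coordinate descent over a named set of conductance
#' parameters, minimizing a weighted squared error on the baseline AP
#' threshold, somatic input resistance, apparent tau and resting potential.
#' The iteration order and multiplicative step schedule are fixed, so the
#' result is reproducible. Stops when every supplied target is met within
#' its tolerance, or errors after `max_iter` rounds with the best-so-far
#' report attached.
#'
#' @param cell starting [build_cell()] model (typically the shipped
#'   defaults, which already satisfy the standard targets).
#' @param targets named list; each element `c(value, tolerance)`. Supported:
#'   `threshold` (mV), `rin` (Mohm), `tau` (ms), `v_rest` (mV).
#' @param params character vector of config paths to tune, from:
#'   `"channels.soma.Nav1.2"`, `"channels.soma.Kv3"`, `"channels.soma.Ih"`,
#'   `"geometry.dendrite.leak_density"`, `"ais.gnav16_density"`.
#' @param weights named numeric weights on the squared target errors.
#' @param max_iter coordinate-descent round cap.
#' @param dt integration step (ms).
#' @return The calibrated `cell_model`, with attribute `"report"`
#'   (data.frame of per-iteration target values) and `"converged"`.
#' @export
calibrate_baseline <- function(cell,
                               targets = list(threshold = c(-43, 0.5),
                                              rin = c(190, 90),
                                              tau = c(6.6, 2.5)),
                               params = c("ais.gnav16_density",
                                          "channels.soma.Kv3",
                                          "geometry.dendrite.leak_density"),
                               weights = c(threshold = 4, rin = 0.01,
                                           tau = 1, v_rest = 1),
                               max_iter = 8,
                               dt = cell$config$simulation$dt) {
  get_path <- function(cfg, path) {
    for (k in strsplit(path, ".", fixed = TRUE)[[1]]) cfg <- cfg[[k]]
    cfg
  }
  set_path <- function(cfg, path, value) {
    ks <- strsplit(path, ".", fixed = TRUE)[[1]]
    expr <- paste0("cfg", paste0("[['", ks, "']]", collapse = ""), " <- value")
    eval(parse(text = expr))
    cfg
  }
  evaluate <- function(cc) {
    out <- list()
    if (!is.null(targets$threshold))
      out$threshold <- as.numeric(measure_threshold(cc, dt = dt))
    if (!is.null(targets$rin) || !is.null(targets$tau)) {
      tr <- run_step_protocol(cc, step_protocol(25, duration = 300, onset = 10),
                              dt = max(dt, 0.02))[[1]]
      if (nrow(detect_aps(tr)) == 0) {
        out$rin <- as.numeric(measure_rin(tr))
        out$tau <- as.numeric(measure_tau(tr))
      } else { out$rin <- NA_real_; out$tau <- NA_real_ }
    }
    if (!is.null(targets$v_rest)) {
      b <- solve_holding_bias(cc, cc$config$simulation$v_hold, verify = FALSE)
      # resting potential: relax without bias
      st <- attr(b, "state")
      sim <- .run_sim(cc, st, dt = 0.02, n_steps = 15000, i_stim = 0,
                      record = cc$idx$soma)
      out$v_rest <- sim$v[nrow(sim$v), 1]
    }
    out
  }
  score <- function(vals) {
    s <- 0; ok <- TRUE
    for (nm in names(targets)) {
      v <- vals[[nm]]
      if (is.null(v) || is.na(v)) { s <- s + 1e3; ok <- FALSE; next }
      err <- v - targets[[nm]][1]
      w <- if (nm %in% names(weights)) weights[[nm]] else 1
      s <- s + w * err^2
      if (abs(err) > targets[[nm]][2]) ok <- FALSE
    }
    list(s = s, ok = ok)
  }

  cfg <- cell$config
  chans <- cell$channels[names(cell$channels) != "leak"]
  vals <- evaluate(cell)
  sc <- score(vals)
  report <- data.frame(iter = 0, param = "(start)",
                       as.data.frame(vals), loss = sc$s)
  if (sc$ok)
    return(structure(cell, report = report, converged = TRUE))

  steps <- c(1.3, 1.12, 1.05)
  best <- list(cfg = cfg, s = sc$s, vals = vals)
  for (it in seq_len(max_iter)) {
    improved <- FALSE
    for (pm in params) {
      cur <- get_path(best$cfg, pm)
      fac <- steps[min(it, length(steps))]
      for (cand in unique(c(cur * fac, cur / fac))) {
        cfg2 <- set_path(best$cfg, pm, cand)
        cc2 <- tryCatch(build_cell(cfg2, channels = chans),
                        error = function(e) NULL)
        if (is.null(cc2)) next
        v2 <- tryCatch(evaluate(cc2), error = function(e) NULL)
        if (is.null(v2)) next
        s2 <- score(v2)
        report <- rbind(report, data.frame(iter = it, param = pm,
                                           as.data.frame(v2), loss = s2$s))
        if (s2$s < best$s) {
          best <- list(cfg = cfg2, s = s2$s, vals = v2)
          improved <- TRUE
          if (s2$ok)
            return(structure(build_cell(cfg2, channels = chans),
                             report = report, converged = TRUE))
        }
      }
    }
    if (!improved) break
  }
  final <- score(best$vals)
  if (!final$ok)
    stop(paste0("calibrate_baseline: iteration cap reached without meeting targets; best: ",
                paste(sprintf("%s=%.3g", names(best$vals), unlist(best$vals)),
                      collapse = ", ")))
  structure(build_cell(best$cfg, channels = chans),
            report = report, converged = TRUE)
}

# run one grid of cell modifications, measuring via `fun(cell)`;
# returns long data.frame with explicit failure markers
.sweep_grid <- function(cell, axes, fun) {
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    args <- c(list(cell), as.list(grid[i, , drop = FALSE]))
    out <- tryCatch({
      cc <- do.call(modify_cell, args)
      cbind(grid[i, , drop = FALSE], fun(cc), status = "ok")
    }, error = function(e)
      cbind(grid[i, , drop = FALSE],
            data.frame(threshold_mV = NA_real_),
            status = paste("failed:", conditionMessage(e))))
    out
  })
  # harmonize columns across ok/failed points
  cols <- Reduce(union, lapply(res, names))
  res <- lapply(res, function(d) { d[setdiff(cols, names(d))] <- NA; d[cols] })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' AP-threshold parameter sweep
#'
#' For each grid point, rebuilds the cell with the modified AIS/axon
#' parameters, re-solves the holding bias, and measures the AP threshold
#' with the standard step protocol ([measure_threshold()]). Deterministic;
#' per-point failures are marked in `status`, never dropped.
#'
#' @param cell the (calibrated) baseline [build_cell()] model.
#' @param ... named sweep axes passed to [modify_cell()]: any of
#'   `ais_length`, `ais_start`, `gkv1_density`, `gnav16_density`,
#'   `axon_diameter`, `ra_axon`, `area_scale`; each a vector of values.
#'   The full factorial grid is swept.
#' @param dt integration step (ms).
#' @return data.frame: one row per grid point with the axis values,
#'   `threshold_mV`, `rheobase_pA`, `status`.
#' @export
sweep_threshold <- function(cell, ..., dt = cell$config$simulation$dt) {
  axes <- list(...)
  stopifnot(length(axes) > 0, all(lengths(axes) > 0))
  .sweep_grid(cell, axes, function(cc) {
    th <- measure_threshold(cc, dt = dt)
    data.frame(threshold_mV = as.numeric(th),
               rheobase_pA = attr(th, "rheobase"))
  })
}

#' EPSC-to-AP time-lag parameter sweep
#'
#' Applies a fixed-strength somatic EPSC at every grid point and measures
#' the lag from EPSC onset to AP onset (10 mV/ms criterion). Grid points
#' that fail to spike are marked explicitly (`spike = FALSE`, `lag_ms` NA).
#'
#' @inheritParams sweep_threshold
#' @param g_peak fixed EPSC peak conductance (nS), default 8.5.
#' @param protocol an [epsc_protocol()] carrying the EPSC kinetics.
#' @return data.frame: axis values, `spike`, `lag_ms`, `v_threshold_mV`,
#'   `status`.
#' @export
sweep_epsc_lag <- function(cell, ..., g_peak = 8.5,
                           protocol = epsc_protocol(),
                           dt = cell$config$simulation$dt) {
  axes <- list(...)
  stopifnot(length(axes) > 0)
  .sweep_grid(cell, axes, function(cc) {
    r <- epsc_response(cc, protocol, g_peak, dt = dt)
    data.frame(spike = r$spike, lag_ms = r$lag_ms,
               v_threshold_mV = r$v_threshold_mV)
  })
}

#' Axon geometry sweep (diameter / axial resistance coupling modes)
#'
#' Sweeps axon diameter and axial resistance under three coupling modes:
#' \describe{
#'   \item{physical}{diameter varies with Ra and membrane area co-varying:
#'     each grid point is a (diameter, Ra) pair; per-area channel densities
#'     are fixed, so total AIS conductance scales with `pi * diameter`.}
#'   \item{ra_only}{Ra varies alone at fixed surface area (fixed diameter,
#'     fixed total conductance).}
#'   \item{area_only}{membrane area (hence total channel conductance and
#'     capacitance) varies alone at fixed Ra, via an area multiplier.}
#' }
#'
#' @param cell the baseline model.
#' @param mode coupling mode (above).
#' @param diameters axon diameters (um; modes physical/area_only).
#' @param ra axial resistances (Mohm/um; modes physical/ra_only). In
#'   physical mode `diameters` and `ra` must have equal length and are
#'   paired, not crossed.
#' @param dt integration step (ms).
#' @return data.frame as [sweep_threshold()], with the mode recorded.
#' @export
sweep_geometry <- function(cell, mode = c("physical", "ra_only", "area_only"),
                           diameters = c(0.6, 0.7, 0.8, 0.9),
                           ra = c(1.1, 1.0, 0.9, 0.8),
                           dt = cell$config$simulation$dt) {
  mode <- match.arg(mode)
  d0 <- cell$config$geometry$axon$diameter
  if (mode == "physical") {
    stopifnot(length(diameters) == length(ra))
    res <- lapply(seq_along(diameters), function(i) {
      sweep_threshold(cell, axon_diameter = diameters[i], ra_axon = ra[i],
                      dt = dt)
    })
    out <- do.call(rbind, res)
  } else if (mode == "ra_only") {
    out <- sweep_threshold(cell, ra_axon = ra, dt = dt)
    out$axon_diameter <- d0
  } else {
    out <- sweep_threshold(cell, area_scale = diameters / d0, dt = dt)
    out$axon_diameter <- diameters
  }
  out$mode <- mode
  out
}
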