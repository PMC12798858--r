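#' Default model-cell configuration
#'
#' Builds the nested configuration list for the three-section fast-spiking
#' interneuron: a point soma (25 pF, 700 Mohm leak, E_leak -68 mV), a
#' 140 um x 0.8 um cylindrical axon carrying the AIS, and a 200 um x 1 um
#' cylindrical dendrite. Axon Cm is 6 fF/um^2 and dendritic Cm 12 fF/um^2.
#' Axial resistance is expressed per unit cable length (Mohm/um), so a
#' stretch of length dx contributes `dx * ra` Mohm in series.
#'
#' Under standard conditions the AIS is 20 um long, starts 10 um from the
#' soma, and carries Nav1.6 and Kv1 at 20 nS/um^2 each; axon Ra is
#' 0.9 Mohm/um at 0.8 um diameter.
#'
#' Channel placement: Nav1.6 + Kv1 + Kv3 in the AIS; Nav1.2 in the soma and
#' proximal dendrite; Kv3 in soma and dendrite; leak, M, Kir and Ih in soma
#' and dendrite; bare axonal membrane is passive.
#'
#' @param ... named overrides merged (deeply) into the defaults, e.g.
#'   `cell_config(ais = list(length = 30, gkv1_density = 0))`.
#' @return A list of class `cell_config`.
#' @export
cell_config <- function(...) {
  cfg <- list(
    geometry = list(
      soma = list(cm_total = 25, r_leak = 700, e_leak = -68),
      axon = list(length = 140, diameter = 0.8, segment_length = 2,
                  cm_per_area = 6, ra = 0.9, leak_density = 0.002,
                  area_scale = 1),
      dendrite = list(length = 200, diameter = 1, segment_length = 10,
                      cm_per_area = 12, ra = 0.58, leak_density = 0.007)
    ),
    ais = list(start = 10, length = 20,
               gnav16_density = 20, gkv1_density = 20, gkv3_density = 10),
    channels = list(
      soma = list(Nav1.2 = 700, Kv3 = 900, M = 2, Kir = 1, Ih = 1.5),
      dendrite = list(Nav1.2 = 0.5, Kv3 = 0.3, M = 0.004, Kir = 0.004,
                      Ih = 0.004, nav12_proximal_frac = 0.2)
    ),
    simulation = list(dt = 0.01, v_hold = -70, settle_ms = 200),
    channel_file = NULL
  )
  over <- list(...)
  if (length(over)) cfg <- .deep_merge(cfg, over)
  class(cfg) <- "cell_config"
  cfg
}

.deep_merge <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .deep_merge(base[[nm]], over[[nm]])
    else
      base[[nm]] <- over[[nm]]
  }
  base
}

#' Assemble the discretized model cell
#'
#' Discretizes the axonal and dendritic cylinders into segments no longer
#' than their `segment_length`, attaches both cables to the point soma, and
#' distributes channel conductances: per-segment total conductance equals
#' density x pi x diameter x segment length, so total AIS conductance scales
#' linearly with AIS length at fixed density.
#'
#' @param config a [cell_config()] (or a plain list with the same shape).
#' @param channels optional channel template list from [load_channels()].
#' @return An object of class `cell_model`: compartment table, conductance
#'   matrix, packed kinetics and bookkeeping indices.
#' @examples
#' cell <- build_cell(cell_config())
#' nrow(cell$comp) # soma + 70 axon + 20 dendrite segments
#' @export
build_cell <- function(config = cell_config(), channels = NULL) {
  cfg <- config
  g <- cfg$geometry
  ais <- cfg$ais

  for (sec in c("axon", "dendrite")) {
    s <- g[[sec]]
    if (s$length <= 0 || s$diameter <= 0)
      stop(sprintf("build_cell: %s length and diameter must be > 0", sec))
    if (s$segment_length > s$length)
      stop(sprintf("build_cell: %s segment_length exceeds section length", sec))
  }
  if (ais$start < 0) stop("build_cell: ais$start must be >= 0")
  if (ais$start + ais$length > g$axon$length)
    stop("build_cell: ais$start + ais$length exceeds axon length (field: ais)")
  for (f in c("gnav16_density", "gkv1_density", "gkv3_density"))
    if (ais[[f]] < 0) stop(sprintf("build_cell: ais$%s must be >= 0", f))

  if (is.null(channels))
    channels <- load_channels(cfg$channel_file)
  specs <- c(channels, list(leak = .leak_spec(g$soma$e_leak)))
  chan_names <- names(specs)

  mk_sec <- function(sec, name) {
    nseg <- ceiling(sec$length / sec$segment_length)
    len <- rep(sec$length / nseg, nseg)
    x0 <- cumsum(len) - len             # proximal edge distance from soma
    data.frame(section = name, x0 = x0, len = len, diam = sec$diameter,
               stringsAsFactors = FALSE)
  }
  axon <- mk_sec(g$axon, "axon")
  dend <- mk_sec(g$dendrite, "dendrite")
  comp <- rbind(
    data.frame(section = "soma", x0 = 0, len = 0, diam = 0,
               stringsAsFactors = FALSE),
    axon, dend)
  n <- nrow(comp)
  i_axon <- which(comp$section == "axon")
  i_dend <- which(comp$section == "dendrite")

  area <- ifelse(comp$section == "soma", NA_real_, pi * comp$diam * comp$len)
  area[i_axon] <- area[i_axon] * g$axon$area_scale
  cm <- numeric(n)
  cm[1] <- g$soma$cm_total
  cm[i_axon] <- area[i_axon] * g$axon$cm_per_area / 1000  # fF -> pF
  cm[i_dend] <- area[i_dend] * g$dendrite$cm_per_area / 1000

  # axial conductances: resistance between segment centres (soma is a point)
  parent <- integer(n); parent[1] <- 0L
  g_ax <- numeric(n)
  link <- function(idx, ra) {
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (j == 1) { parent[i] <<- 1L; r <- ra * comp$len[i] / 2 }
      else { parent[i] <<- idx[j - 1]; r <- ra * (comp$len[i] + comp$len[idx[j - 1]]) / 2 }
      g_ax[i] <<- 1000 / r  # Mohm -> nS
    }
  }
  link(i_axon, g$axon$ra)
  link(i_dend, g$dendrite$ra)

  # conductance matrix
  gbar <- matrix(0, n, length(specs), dimnames = list(NULL, chan_names))
  # AIS segments: those whose centre lies in [start, start + length)
  centre <- comp$x0 + comp$len / 2
  in_ais <- comp$section == "axon" & centre >= ais$start & centre < ais$start + ais$length
  if (!any(in_ais)) stop("build_cell: AIS covers no axon segment")
  gbar[in_ais, "Nav1.6"] <- ais$gnav16_density * area[in_ais]
  gbar[in_ais, "Kv1"] <- ais$gkv1_density * area[in_ais]
  gbar[in_ais, "Kv3"] <- ais$gkv3_density * area[in_ais]
  gbar[i_axon, "leak"] <- g$axon$leak_density * area[i_axon]

  soma_ch <- cfg$channels$soma
  for (nm in names(soma_ch)) gbar[1, nm] <- soma_ch[[nm]]
  gbar[1, "leak"] <- 1000 / g$soma$r_leak

  dch <- cfg$channels$dendrite
  prox <- comp$section == "dendrite" &
    centre < dch$nav12_proximal_frac * g$dendrite$length
  gbar[prox, "Nav1.2"] <- dch$Nav1.2 * area[prox]
  for (nm in c("Kv3", "M", "Kir", "Ih"))
    gbar[i_dend, nm] <- dch[[nm]] * area[i_dend]
  gbar[i_dend, "leak"] <- g$dendrite$leak_density * area[i_dend]
  if (any(gbar < 0)) stop("build_cell: negative conductance in configuration")

  ais_idx <- which(in_ais)
  structure(list(
    comp = cbind(comp, area = area, cm = cm, parent = parent, g_ax = g_ax),
    gbar = gbar,
    kin = .kin_matrix(specs),
    channels = specs,
    config = cfg,
    idx = list(soma = 1L, axon = i_axon, dendrite = i_dend, ais = ais_idx,
               ais_mid = ais_idx[ceiling(length(ais_idx) / 2)])
  ), class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<cell_model> %d compartments (axon %d, dendrite %d)\n  AIS: %g um at %g um from soma; gNav1.6 %g, gKv1 %g nS/um^2\n  axon: %g x %g um, Ra %g Mohm/um\n",
    nrow(x$comp), length(x$idx$axon), length(x$idx$dendrite),
    cfg$ais$length, cfg$ais$start, cfg$ais$gnav16_density, cfg$ais$gkv1_density,
    cfg$geometry$axon$length, cfg$geometry$axon$diameter, cfg$geometry$axon$ra))
  invisible(x)
}

#' Rebuild a cell with modified AIS / axon parameters
#'
#' Convenience wrapper used by the sweep experiments: applies scalar
#' modifications to the cell's configuration and rebuilds it.
#'
#' @param cell a [build_cell()] result.
#' @param ais_length,ais_start AIS geometry (um).
#' @param gkv1_density,gnav16_density AIS channel densities (nS/um^2).
#' @param axon_diameter axon diameter (um).
#' @param ra_axon axial resistance per unit length (Mohm/um).
#' @param area_scale multiplier on axonal membrane area (scales both
#'   capacitance and total channel conductance at fixed density).
#' @return A new `cell_model`.
#' @export
modify_cell <- function(cell, ais_length = NULL, ais_start = NULL,
                        gkv1_density = NULL, gnav16_density = NULL,
                        axon_diameter = NULL, ra_axon = NULL,
                        area_scale = NULL) {
  cfg <- cell$config
  if (!is.null(ais_length)) cfg$ais$length <- ais_length
  if (!is.null(ais_start)) cfg$ais$start <- ais_start
  if (!is.null(gkv1_density)) cfg$ais$gkv1_density <- gkv1_density
  if (!is.null(gnav16_density)) cfg$ais$gnav16_density <- gnav16_density
  if (!is.null(axon_diameter)) cfg$geometry$axon$diameter <- axon_diameter
  if (!is.null(ra_axon)) cfg$geometry$axon$ra <- ra_axon
  if (!is.null(area_scale)) cfg$geometry$axon$area_scale <- area_scale
  build_cell(cfg, channels = cell$channels[names(cell$channels) != "leak"])
}
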