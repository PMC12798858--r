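# Configuration loading/validation, trace CSV round-trip, run manifests.

# allowed keys per config section (schema)
.config_schema <- list(
  geometry = list(
    soma = c("cm_total", "r_leak", "e_leak"),
    axon = c("length", "diameter", "segment_length", "cm_per_area", "ra",
             "leak_density", "area_scale"),
    dendrite = c("length", "diameter", "segment_length", "cm_per_area", "ra",
                 "leak_density")),
  ais = c("start", "length", "gnav16_density", "gkv1_density", "gkv3_density"),
  channels = list(
    soma = c("Nav1.2", "Kv3", "M", "Kir", "Ih"),
    dendrite = c("Nav1.2", "Kv3", "M", "Kir", "Ih", "nav12_proximal_frac")),
  simulation = c("dt", "v_hold", "settle_ms"),
  channel_file = NULL
)

.check_keys <- function(x, schema, path) {
  if (is.character(schema)) {
    bad <- setdiff(names(x), schema)
    if (length(bad))
      stop(sprintf("load_config: unknown key(s) under %s: %s", path,
                   paste(bad, collapse = ", ")))
  } else if (is.list(schema)) {
    bad <- setdiff(names(x), names(schema))
    if (length(bad))
      stop(sprintf("load_config: unknown key(s) under %s: %s", path,
                   paste(bad, collapse = ", ")))
    for (nm in names(x))
      if (!is.null(schema[[nm]]))
        .check_keys(x[[nm]], schema[[nm]], paste(path, nm, sep = "$"))
  }
  invisible(TRUE)
}

#' Load and validate a model configuration file
#'
#' Reads a YAML model configuration, rejects unknown keys (they are errors,
#' not silently ignored), applies package defaults for everything omitted
#' and validates the physical invariants (units follow the repo-wide
#' convention: mV, ms, nS, pA, pF, um; axial resistance in Mohm per um).
#'
#' @param path YAML file path.
#' @return A validated [cell_config()], with attribute `"digest"` (stable
#'   hash of the canonicalized configuration).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("load_config: file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known_top <- c(names(.config_schema), "protocols", "sweeps")
  bad <- setdiff(names(raw), known_top)
  if (length(bad))
    stop(sprintf("load_config: unknown top-level key(s): %s",
                 paste(bad, collapse = ", ")))
  model_part <- raw[intersect(names(raw), names(.config_schema))]
  .check_keys(model_part, .config_schema, "config")
  cfg <- do.call(cell_config, model_part)
  # invariant checks (negative densities / impossible geometry fail here)
  for (f in names(cfg$ais))
    if (cfg$ais[[f]] < 0)
      stop(sprintf("load_config: ais$%s violates non-negativity", f))
  if (cfg$simulation$dt <= 0) stop("load_config: simulation$dt must be > 0")
  build_cell(cfg) # full structural validation; discarded
  attr(cfg, "protocols") <- raw$protocols
  attr(cfg, "sweeps") <- raw$sweeps
  attr(cfg, "digest") <- config_digest(cfg)
  cfg
}

#' Stable digest of a configuration
#'
#' FNV-1a hash of the canonical JSON serialization; identical configurations
#' yield identical digests across runs and platforms.
#'
#' @param cfg a [cell_config()] (or any serializable list).
#' @return 8-character hexadecimal string.
#' @export
config_digest <- function(cfg) {
  attributes(cfg) <- attributes(cfg)["names"]
  drop_null <- function(x) {
    if (!is.list(x)) return(x)
    x <- x[!vapply(x, is.null, TRUE)]
    lapply(x, drop_null)
  }
  s <- jsonlite::toJSON(drop_null(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(s)))
  # 32-bit FNV-1a in double arithmetic: the xor only touches the low byte,
  # and the multiply is split 16/16 so no intermediate exceeds 2^53
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write / read voltage traces as CSV
#'
#' Canonical trace store: CSV with header
#' `time_ms,v_soma_mV[,v_ais_mV],i_stim_pA,g_syn_nS`, floats at 6
#' significant digits. Multi-sweep files carry an additional leading
#' `sweep_id` column.
#'
#' @param trace a [voltage_trace()] or list of traces (multi-sweep).
#' @param path output file.
#' @return `write_trace`: the path, invisibly. `read_trace`: a
#'   [voltage_trace()] or (for multi-sweep files) list of traces.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "voltage_trace")) {
    d <- as.data.frame(trace)
  } else {
    d <- do.call(rbind, lapply(seq_along(trace), function(i)
      cbind(sweep_id = i, as.data.frame(trace[[i]]))))
  }
  num <- vapply(d, is.numeric, TRUE) & names(d) != "sweep_id"
  d[num] <- lapply(d[num], signif, digits = 6)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_ms", "v_soma_mV")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("read_trace: missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  one <- function(dd) {
    tt <- dd$time_ms
    if (length(tt) > 2 && max(abs(diff(tt) - diff(tt[1:2]))) > 1e-6)
      stop("read_trace: non-uniform time base")
    voltage_trace(tt, dd$v_soma_mV,
                  v_ais = dd$v_ais_mV,
                  i_stim = if (!is.null(dd$i_stim_pA)) dd$i_stim_pA else NULL,
                  g_syn = if (!is.null(dd$g_syn_nS)) dd$g_syn_nS else NULL,
                  meta = list(source = path))
  }
  if (!is.null(d$sweep_id)) {
    ids <- unique(d$sweep_id)
    out <- lapply(ids, function(i) one(d[d$sweep_id == i, , drop = FALSE]))
    names(out) <- ids
    if (length(out) == 1) out[[1]] else out
  } else one(d)
}

#' Run manifest
#'
#' Provenance record written alongside pipeline outputs: configuration
#' digest, package version, seeds, timestamps and per-stage status/warnings.
#'
#' @param config the configuration used (for its digest).
#' @param seed seed(s) in effect.
#' @return An environment of class `run_manifest`; use [manifest_note()] to
#'   append stage entries and [write_manifest()] to serialize as JSON.
#' @export
run_manifest <- function(config = NULL, seed = NULL) {
  m <- new.env(parent = emptyenv())
  m$config_digest <- if (!is.null(config)) config_digest(config) else NA_character_
  m$package_version <- as.character(utils::packageVersion("aispike"))
  m$seed <- seed
  m$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  m$stages <- list()
  class(m) <- "run_manifest"
  m
}

#' @rdname run_manifest
#' @param manifest a [run_manifest()].
#' @param stage stage name.
#' @param status status string ("ok", "warning", "failed", ...).
#' @param ... further fields (e.g. warnings, counts) stored with the stage.
#' @export
manifest_note <- function(manifest, stage, status = "ok", ...) {
  manifest$stages[[stage]] <- c(list(status = status,
                                     time = format(Sys.time(), "%H:%M:%S")),
                                list(...))
  invisible(manifest)
}

#' @rdname run_manifest
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(
    list(config_digest = manifest$config_digest,
         package_version = manifest$package_version,
         seed = manifest$seed, created = manifest$created,
         stages = manifest$stages),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
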