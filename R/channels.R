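#' Load channel kinetics definitions
#'
#' Reads a YAML channel parameter file (one record per channel with activation
#' and optional inactivation [gate_kinetics()]) and returns a named list of
#' [channel_spec()] templates. Conductance values are assigned later by the
#' cell model, so the templates carry `g = 0`.
#'
#' The packaged default file (`params/channels.yaml`) holds the fast-spiking
#' interneuron channel set: Nav1.6, Nav1.2, Kv1, Kv3, M, Kir, Ih.
#'
#' @param path path to a YAML file; `NULL` loads the packaged defaults.
#' @return Named list of `channel_spec` objects.
#' @export
load_channels <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("params", "channels.yaml", package = "aispike")
  raw <- yaml::read_yaml(path)
  if (is.null(raw$channels)) stop("channel file must have a top-level 'channels' key")
  specs <- lapply(names(raw$channels), function(nm) {
    ch <- raw$channels[[nm]]
    bad <- setdiff(names(ch), c("p", "e_rev", "activation", "inactivation"))
    if (length(bad))
      stop(sprintf("channel '%s': unknown key(s): %s", nm, paste(bad, collapse = ", ")))
    act <- if (!is.null(ch$activation)) do.call(gate_kinetics, ch$activation)
    ina <- if (!is.null(ch$inactivation)) do.call(gate_kinetics, ch$inactivation)
    channel_spec(nm, 0, ch$p, ch$e_rev, activation = act, inactivation = ina)
  })
  names(specs) <- names(raw$channels)
  specs
}

# leak pseudo-channel (ungated)
.leak_spec <- function(e_leak) channel_spec("leak", 0, 0L, e_leak)
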