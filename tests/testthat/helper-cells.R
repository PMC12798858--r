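# shared fixtures: cells built in code, no stored data

# fully passive cell: all voltage-gated conductances and cable leaks zero,
# so the soma leak (700 Mohm) is the only resistive path
passive_cell <- function(...) {
  build_cell(cell_config(
    ais = list(gnav16_density = 0, gkv1_density = 0, gkv3_density = 0),
    channels = list(soma = list(Nav1.2 = 0, Kv3 = 0, M = 0, Kir = 0, Ih = 0),
                    dendrite = list(Nav1.2 = 0, Kv3 = 0, M = 0, Kir = 0, Ih = 0)),
    geometry = list(axon = list(leak_density = 0),
                    dendrite = list(leak_density = 0)),
    ...))
}

# standard active cell under the shipped defaults
standard_cell <- function(...) build_cell(cell_config(...))

# an effectively isolated soma: vestigial cables with negligible area/coupling
isolated_soma_cell <- function() {
  build_cell(cell_config(
    ais = list(start = 0.2, length = 0.4, gnav16_density = 0,
               gkv1_density = 0, gkv3_density = 0),
    channels = list(soma = list(Nav1.2 = 0, Kv3 = 0, M = 0, Kir = 0, Ih = 0),
                    dendrite = list(Nav1.2 = 0, Kv3 = 0, M = 0, Kir = 0, Ih = 0)),
    geometry = list(
      axon = list(length = 1, diameter = 0.01, segment_length = 0.5,
                  leak_density = 0, ra = 1e5),
      dendrite = list(length = 1, diameter = 0.01, segment_length = 0.5,
                      leak_density = 0, ra = 1e5))))
}

# direct linear-algebra steady state of the passive discretized network:
# solves G v = b for the injected-current steady state (oracle for Rin)
passive_steady_oracle <- function(cell, i_soma_pA) {
  n <- nrow(cell$comp)
  leak <- cell$gbar[, "leak"]
  e_leak <- cell$config$geometry$soma$e_leak
  G <- diag(leak, n)
  p <- cell$comp$parent; ga <- cell$comp$g_ax
  for (i in 2:n) {
    G[i, i] <- G[i, i] + ga[i]
    G[p[i], p[i]] <- G[p[i], p[i]] + ga[i]
    G[i, p[i]] <- G[i, p[i]] - ga[i]
    G[p[i], i] <- G[p[i], i] - ga[i]
  }
  b <- leak * e_leak
  b[1] <- b[1] + i_soma_pA
  solve(G, b)
}
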