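# small networks and synthetic objects used across tests

# uniform excitable cable
toy_chain <- function(n = 5, d = 100, alpha = 1, a = 0.15, eps0 = 0.02,
                      mu1 = 0.1, ct = 300) {
  labs <- paste0("C", seq_len(n))
  cells <- data.frame(label = labs, zone = "atrial", k = 8, a1 = a, a2 = a,
                      mu1 = mu1, mu2 = 0.3, eps0 = eps0, ct = ct,
                      stringsAsFactors = FALSE)
  jn <- data.frame(from = labs[-n], to = labs[-1], d = d, alpha = alpha,
                   stringsAsFactors = FALSE)
  custom_topology(cells, jn)
}

# a two-cell network with one junction
toy_pair <- function(d = 10, alpha = 1) toy_chain(n = 2, d = d,
                                                  alpha = alpha)

# hand-built trace object (for detector tests)
synthetic_trace <- function(time, u, topo = toy_chain(ncol(u))) {
  colnames(u) <- topo$cells$label[seq_len(ncol(u))]
  structure(list(time = time, u = u, v = u * 0,
                 activations = NULL,
                 schedule = stimulus_schedule(NULL, horizon = max(time)),
                 opts = solver_options(), topo = topo),
            class = "avn_trace")
}

# activation table from a plain data frame
synthetic_table <- function(df, topo = build_topology()) {
  df <- df[order(df$time), ]
  rownames(df) <- NULL
  structure(df, topo = topo, class = c("activation_table", "data.frame"))
}

default_topo_cached <- local({
  topo <- NULL
  function() {
    if (is.null(topo)) topo <<- build_topology()
    topo
  }
})
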