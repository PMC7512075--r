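# Hand-built layouts for engine-level tests.

make_layout <- function(neuron_pos, neuron_type, astro_pos, synapses,
                        astro_edges = matrix(integer(0), 0, 2),
                        domain_size = 10, seed = 1L) {
  if (is.null(synapses$astro)) synapses$astro <- NA_integer_
  structure(list(neuron_pos = neuron_pos, neuron_type = neuron_type,
                 astro_pos = astro_pos, synapses = synapses,
                 astro_edges = astro_edges, domain_size = domain_size,
                 seed = as.integer(seed)),
            class = "network_layout")
}

# one isolated neuron, no synapses, no astrocytes
isolated_neuron_layout <- function() {
  make_layout(matrix(c(5, 5), 1, 2), "E",
              matrix(numeric(0), 0, 2),
              data.frame(pre = integer(0), post = integer(0),
                         type = character(0), astro = integer(0)))
}

# two neurons, one excitatory synapse 1 -> 2, one astrocyte on the synapse
two_neuron_layout <- function() {
  make_layout(matrix(c(4, 5, 6, 5), 2, 2, byrow = TRUE), c("E", "E"),
              matrix(c(5, 5), 1, 2),
              data.frame(pre = 1L, post = 2L, type = "E", astro = 1L))
}
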