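# shared helpers: small deterministic nets and configs used across tests

dyn1 <- function(...) dynamics_config(t_refr = 1, ...)

small_net <- function(seed = 1, n_hidden = 30, d0 = 2, p_inh = 0, ...) {
  generate_network(topology_config(n_hidden = n_hidden, d0 = d0,
                                   p_inh = p_inh, seed = seed, ...))
}

# input -> A -> output with individual weights
two_step_net <- function(w_in, w_out) {
  neurons <- data.frame(id = 1:3, x = c(0, 1, 2), y = 1,
                        role = c("input", "hidden", "output"),
                        inhibitory = FALSE, stringsAsFactors = FALSE)
  synapses <- data.frame(pre = c(1, 2), post = c(2, 3),
                         weight = c(w_in, w_out))
  spatplast:::new_network(neurons, synapses, input_ids = 1L, output_id = 3L,
                          L = 2)
}

# one input feeding k parallel hidden neurons that all project to the output;
# per-edge weights, optional inhibitory flags on the hidden neurons
fan_net <- function(w_in, w_out, inhibitory = rep(FALSE, length(w_in))) {
  k <- length(w_in)
  L <- max(2, k)
  neurons <- data.frame(id = seq_len(k + 2),
                        x = c(0, rep(1, k), 2),
                        y = c(1, seq_len(k), 1),
                        role = c("input", rep("hidden", k), "output"),
                        inhibitory = c(FALSE, inhibitory, FALSE),
                        stringsAsFactors = FALSE)
  synapses <- data.frame(
    pre = c(rep(1, k), 1 + seq_len(k)),
    post = c(1 + seq_len(k), rep(k + 2, k)),
    weight = c(w_in, w_out))
  spatplast:::new_network(neurons, synapses, input_ids = 1L,
                          output_id = k + 2L, L = L)
}
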