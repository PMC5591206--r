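# Hand-built reference networks with exactly known behaviour. These give the
# test suite ground truth that is independent of the random generator.

#' Purely excitatory XOR motif
#'
#' An 8-neuron network (2 inputs, 5 hidden, 1 output) with non-negative
#' weights only (1.0 and 0.99) that computes XOR on its two inputs when run
#' with a refractory time of one step. Inhibition is generated purely by
#' timing: with both inputs active, the coincidence-detecting hidden neuron
#' fires one step earlier than in the single-input case, so the delayed
#' pathway stimulates the penultimate neuron exactly while it is refractory;
#' it then fires only once, and a single spike through its sub-unit synapse
#' cannot drive the output over threshold. With one input active the delayed
#' stimulation lands after the refractory window, the penultimate neuron
#' fires twice and its two spikes sum above threshold.
#'
#' Wiring (weights in parentheses): inputs 1,2 -> 3 (1.0) and -> 4 (0.99);
#' 3 -> 4 (1.0), 3 -> 6 (1.0); 4 -> 5 (1.0); 5 -> 7 (1.0); 7 -> 6 (1.0);
#' 6 -> 8 (0.99), with 8 the output neuron.
#'
#' @return a `spatplast_network` with an `expected_truth_table` attribute
#'   (data frame `in1`, `in2`, `target`).
#' @examples
#' net <- xor_motif()
#' run_trial(net, c(1, 1), dynamics_config(t_refr = 1))$output_fired
#' @export
xor_motif <- function() {
  neurons <- data.frame(
    id = 1:8,
    x = c(0, 0, 1.5, 1.5, 3, 3, 4.5, 6),
    y = c(2, 4, 4, 2, 2, 4, 2, 3),
    role = c("input", "input", rep("hidden", 5), "output"),
    inhibitory = FALSE,
    stringsAsFactors = FALSE)
  synapses <- data.frame(
    pre  = c(1, 2, 1, 2, 3, 3, 4, 5, 7, 6),
    post = c(3, 3, 4, 4, 4, 6, 5, 7, 6, 8),
    weight = c(1, 1, 0.99, 0.99, 1, 1, 1, 1, 1, 0.99))
  net <- new_network(neurons, synapses, input_ids = 1:2, output_id = 8L,
                     L = 6, config = NULL, subclass = "spatplast_fixture")
  attr(net, "expected_truth_table") <- data.frame(
    in1 = c(0, 1, 0, 1), in2 = c(0, 0, 1, 1), target = c(0, 1, 1, 0))
  net
}

#' Linear chain fixture
#'
#' `input -> hidden_1 -> ... -> hidden_length -> output` with one uniform
#' weight on every synapse: the minimal deterministic network for verifying
#' propagation timing, refractoriness, transmitter depletion and
#' initialization boost counts.
#'
#' @param length number of hidden neurons in the chain (>= 1).
#' @param weight uniform synaptic weight (> 0).
#' @return a `spatplast_network` with a single input neuron.
#' @export
chain_fixture <- function(length, weight) {
  if (length < 1 || length != round(length)) .stopf("length must be >= 1")
  if (!is.numeric(weight) || weight <= 0) .stopf("weight must be > 0")
  n <- length + 2L
  neurons <- data.frame(
    id = seq_len(n), x = seq_len(n) - 1, y = 0,
    role = c("input", rep("hidden", length), "output"),
    inhibitory = FALSE, stringsAsFactors = FALSE)
  # the square is notional for fixtures; take L wide enough to hold the line
  neurons$y <- (n - 1) / 2
  synapses <- data.frame(pre = seq_len(n - 1), post = 2:n, weight = weight)
  net <- new_network(neurons, synapses, input_ids = 1L, output_id = n,
                     L = n - 1, config = NULL,
                     subclass = "spatplast_fixture")
  net
}

#' The 2-input XOR rule
#'
#' @return a `spatplast_rule` over all four 2-bit patterns with XOR targets.
#' @export
xor_rule <- function() {
  new_rule(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
           c(0, 1, 1, 0), name = "xor2")
}

#' Truth table computed by a network
#'
#' Runs every row of `patterns` through [run_trial()] and reports the
#' produced output bits.
#'
#' @param net a `spatplast_network`.
#' @param patterns 0/1 matrix, one pattern per row; defaults to all
#'   combinations over the network's inputs.
#' @param cfg a [dynamics_config()].
#' @return data frame of input bits plus a `produced` column.
#' @export
truth_table <- function(net, patterns = NULL, cfg = dynamics_config()) {
  k <- length(net$input_ids)
  if (is.null(patterns)) {
    patterns <- as.matrix(expand.grid(rep(list(0:1), k)))
    colnames(patterns) <- NULL
  }
  produced <- apply(patterns, 1, function(p)
    as.integer(run_trial(net, p, cfg)$output_fired))
  out <- as.data.frame(patterns)
  names(out) <- paste0("in", seq_len(k))
  out$produced <- produced
  out
}
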