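#' Learning configuration
#'
#' Parameters of the distance-dependent adaptation rule. After a wrong
#' answer every synapse activated during the trial changes by
#' `alpha * w * n_act * K(r)`, where `r` is the Euclidean distance between
#' the output neuron and the postsynaptic neuron and `K` is a spatial kernel
#' decaying on the learning length `r0`. Weights are confined to
#' `[0, omega_max]`.
#'
#' @param r0 learning length: spatial decay scale of the adaptation signal
#'   released at the output neuron (length units, > 0).
#' @param alpha adaptation strength (default 0.001).
#' @param kernel `"exponential"` (`exp(-r/r0)`) or `"gaussian"`
#'   (`exp(-r^2 / (2 r0^2))`).
#' @param omega_max maximum synaptic strength (default 2).
#' @param critical_factor multiplicative global growth applied per silent
#'   pass during [critical_initialization()] (default 0.001).
#' @param boost_factor multiplicative global growth applied during training
#'   when no signal reaches the output neuron (default `alpha`). Numerically
#'   equal to `critical_factor` by default but conceptually distinct.
#' @param max_boosts cap on initialization boosts before giving up.
#' @return an object of class `spatplast_learning_config`.
#' @export
learning_config <- function(r0, alpha = 0.001,
                            kernel = c("exponential", "gaussian"),
                            omega_max = 2, critical_factor = 0.001,
                            boost_factor = alpha, max_boosts = 1e5) {
  kernel <- match.arg(kernel)
  if (!is.numeric(r0) || length(r0) != 1 || !is.finite(r0) || r0 <= 0)
    .stopf("r0 must be a positive length")
  if (!is.numeric(alpha) || alpha <= 0) .stopf("alpha must be > 0")
  if (!is.numeric(omega_max) || omega_max <= 0) .stopf("omega_max must be > 0")
  if (critical_factor <= 0 || boost_factor <= 0)
    .stopf("boost factors must be > 0")
  structure(list(r0 = r0, alpha = alpha, kernel = kernel,
                 omega_max = omega_max, critical_factor = critical_factor,
                 boost_factor = boost_factor,
                 max_boosts = as.integer(max_boosts)),
            class = "spatplast_learning_config")
}

#' Spatial decay factor of the adaptation signal
#'
#' `exp(-r/r0)` for the exponential kernel, `exp(-r^2/(2 r0^2))` for the
#' Gaussian; equals 1 at the output neuron and decreases strictly with
#' distance.
#'
#' @param r distance(s) from the output neuron (>= 0).
#' @param cfg a [learning_config()].
#' @return dimensionless factor(s) in `(0, 1]`.
#' @export
kernel_factor <- function(r, cfg) {
  stopifnot(inherits(cfg, "spatplast_learning_config"))
  if (any(r < 0)) .stopf("distances must be non-negative")
  switch(cfg$kernel,
         exponential = exp(-r / cfg$r0),
         gaussian = exp(-r^2 / (2 * cfg$r0^2)))
}

#' Apply one distance-dependent adaptation event
#'
#' For every synapse activated in the trial (`n_act > 0`) the weight
#' magnitude changes by `alpha * w * n_act * K(r)`. The `strengthen`
#' direction pushes the network towards firing: excitatory weights grow and
#' inhibitory weights shrink; `weaken` does the reverse. Weights are clamped
#' to `[0, omega_max]`; untouched synapses keep their weight.
#'
#' @param net a `spatplast_network`.
#' @param record a [run_trial()] result for the failing presentation.
#' @param direction `"strengthen"` or `"weaken"`.
#' @param cfg a [learning_config()].
#' @return the adapted network.
#' @export
adapt <- function(net, record, direction = c("strengthen", "weaken"), cfg) {
  direction <- match.arg(direction)
  stopifnot(inherits(cfg, "spatplast_learning_config"))
  n_act <- record$n_act
  if (length(n_act) != nrow(net$synapses))
    .stopf("trial record does not match the network's synapse count")
  w <- net$synapses$weight
  k <- kernel_factor(output_distances(net), cfg)
  dir <- if (direction == "strengthen") 1 else -1
  delta <- cfg$alpha * w * n_act * k
  net$synapses$weight <- .clamp(w + dir * synapse_signs(net) * delta,
                                0, cfg$omega_max)
  net
}

#' Globally strengthen all synapses
#'
#' Multiplies every weight by `1 + factor`, capped at `omega_max`. Used both
#' for the critical-point initialization and as the weak-activity boost when
#' a presentation leaves the output neuron's voltage unchanged.
#'
#' @param net a `spatplast_network`.
#' @param factor relative increase (> 0).
#' @param omega_max weight cap (default 2).
#' @return the boosted network.
#' @export
boost_all <- function(net, factor, omega_max = 2) {
  if (!is.numeric(factor) || factor <= 0) .stopf("factor must be > 0")
  net$synapses$weight <- pmin(net$synapses$weight * (1 + factor), omega_max)
  net
}

#' Bring a network to the critical point
#'
#' Starting from the weak initial weights, presents all patterns of the rule;
#' whenever a complete pass leaves the output neuron silent for every input,
#' all weights are multiplied by `1 + critical_factor`. The procedure stops
#' the first time any input makes the output neuron fire: the network then
#' sits near the critical weight level at which activity just reaches the
#' output, the regime in which learning starts.
#'
#' @param net a freshly initialized `spatplast_network`.
#' @param rule a [load_rule()] result.
#' @param dyn_cfg a [dynamics_config()].
#' @param learn_cfg a [learning_config()].
#' @return list with the boosted `net` and the number of `boosts` applied.
#' @export
critical_initialization <- function(net, rule, dyn_cfg = dynamics_config(),
                                    learn_cfg) {
  stopifnot(inherits(rule, "spatplast_rule"),
            inherits(learn_cfg, "spatplast_learning_config"))
  if (ncol(rule$patterns) != length(net$input_ids))
    .stopf("rule input width does not match the network")
  n <- nrow(net$neurons)
  res <- cpp_critical_init(
    n, net$synapses$pre, net$synapses$post, net$synapses$weight,
    synapse_signs(net), net$output_id,
    rule$patterns, net$input_ids,
    learn_cfg$critical_factor, learn_cfg$omega_max, learn_cfg$max_boosts,
    dyn_cfg$v_max, dyn_cfg$delta_eta, dyn_cfg$t_refr,
    dyn_cfg$activation == "linear",
    isTRUE(dyn_cfg$refractory_blocks_same_step),
    .resolve_step_cap(dyn_cfg, n))
  net$synapses$weight <- res$weight
  list(net = net, boosts = res$boosts)
}
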