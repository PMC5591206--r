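#' Topology configuration for a spatially embedded random network
#'
#' Describes a network of `n_hidden` neurons placed uniformly at random in a
#' square of side `L = sqrt(n_hidden / density)`, so that the area grows
#' proportionally to the number of neurons and the neuron density stays
#' constant across system sizes. Four input neurons sit on the left edge and
#' one output neuron on the right edge. Each connection of a hidden neuron is
#' drawn by sampling a distance from an exponential distribution with mean
#' `d0` and linking to the neuron whose Euclidean distance is closest to the
#' draw.
#'
#' @param n_hidden number of hidden neurons (positive integer, >= `out_degree` + 1).
#' @param d0 characteristic synaptic length: mean of the exponential
#'   connection-distance distribution (length units, > 0).
#' @param p_inh fraction of hidden neurons flagged inhibitory, in `[0, 1)`.
#'   Input and output neurons are always excitatory.
#' @param out_degree outgoing connections per input/hidden neuron (default 10);
#'   also the output neuron's in-degree.
#' @param density neurons per unit area (> 0); fixes `L = sqrt(n_hidden / density)`.
#' @param seed optional RNG seed stored for reproducible generation.
#' @return an object of class `spatplast_topology_config`.
#' @seealso [generate_network()]
#' @export
topology_config <- function(n_hidden, d0 = 2, p_inh = 0, out_degree = 10,
                            density = 1, seed = NULL) {
  if (!is.numeric(n_hidden) || length(n_hidden) != 1 || n_hidden < 1 ||
      n_hidden != round(n_hidden))
    .stopf("n_hidden must be a positive integer")
  if (!is.numeric(d0) || length(d0) != 1 || !is.finite(d0) || d0 <= 0)
    .stopf("d0 must be a positive length")
  if (!is.numeric(p_inh) || p_inh < 0 || p_inh >= 1)
    .stopf("p_inh must lie in [0, 1)")
  if (out_degree < 1 || out_degree != round(out_degree))
    .stopf("out_degree must be a positive integer")
  if (n_hidden - 1 < out_degree)
    .stopf("need at least out_degree + 1 hidden neurons (got %d)", n_hidden)
  if (!is.numeric(density) || density <= 0)
    .stopf("density must be > 0")
  structure(list(n_hidden = as.integer(n_hidden), d0 = d0, p_inh = p_inh,
                 out_degree = as.integer(out_degree), density = density,
                 L = sqrt(n_hidden / density), seed = seed),
            class = "spatplast_topology_config")
}

#' Sample synaptic connection distances
#'
#' Draws from the exponential connection-length distribution
#' `p(d) = (1/d0) exp(-d/d0)`, whose mean is `d0`.
#'
#' @param n number of draws.
#' @param d0 characteristic synaptic length (> 0).
#' @return numeric vector of `n` distances.
#' @export
sample_connection_distance <- function(n, d0) {
  if (!is.numeric(d0) || length(d0) != 1 || !is.finite(d0) || d0 <= 0)
    .stopf("d0 must be a positive length")
  rexp(n, rate = 1 / d0)
}

#' Place the neurons of a network
#'
#' Hidden neurons are scattered uniformly in the `[0, L]^2` square; the four
#' input neurons sit on the left edge at heights `L/5, 2L/5, 3L/5, 4L/5`; the
#' output neuron sits at `(L, L/2)`. Hidden neurons are flagged inhibitory
#' independently with probability `p_inh`; input and output neurons never are.
#'
#' Neuron ids: inputs `1:4`, hidden `5:(n_hidden + 4)`, output `n_hidden + 5`.
#'
#' @param config a [topology_config()].
#' @return data frame with columns `id`, `x`, `y`, `role`, `inhibitory`.
#' @export
place_neurons <- function(config) {
  stopifnot(inherits(config, "spatplast_topology_config"))
  L <- config$L
  n <- config$n_hidden
  n_in <- 4L
  ids <- seq_len(n + n_in + 1L)
  x <- c(rep(0, n_in), runif(n, 0, L), L)
  y <- c(L / 5 * seq_len(n_in), runif(n, 0, L), L / 2)
  role <- c(rep("input", n_in), rep("hidden", n), "output")
  inhib <- c(rep(FALSE, n_in),
             runif(n) < config$p_inh,
             FALSE)
  data.frame(id = ids, x = x, y = y, role = role, inhibitory = inhib,
             stringsAsFactors = FALSE)
}

# deterministic nearest-to-d pick among available candidates; ties resolve to
# the first (lowest-id) candidate
.pick_nearest <- function(dist, avail, d) {
  score <- abs(dist - d)
  score[!avail] <- Inf
  which.min(score)
}

#' Wire a placed network
#'
#' Builds the directed synapse list. The output neuron first receives one
#' synapse from each of its `out_degree` nearest nodes (that connection counts
#' towards the source's out-degree). Each input neuron then connects to its
#' nearest hidden neighbours, and each hidden neuron fills its remaining
#' out-degree by repeatedly drawing a distance `d` from the exponential
#' distribution and connecting to the still-unconnected hidden neuron whose
#' Euclidean distance is closest to `d`. Self-loops and duplicate edges are
#' excluded; input neurons receive no synapses; the output neuron sends none.
#'
#' @param neurons data frame from [place_neurons()].
#' @param config the matching [topology_config()].
#' @return an unweighted network object of class `spatplast_network`
#'   (weights `NA` until [initialize_weights()]).
#' @export
wire_network <- function(neurons, config) {
  stopifnot(inherits(config, "spatplast_topology_config"))
  n_total <- nrow(neurons)
  input_ids <- neurons$id[neurons$role == "input"]
  hidden_ids <- neurons$id[neurons$role == "hidden"]
  output_id <- neurons$id[neurons$role == "output"]
  k <- config$out_degree
  x <- neurons$x
  y <- neurons$y

  pre <- integer(0)
  post <- integer(0)

  # output neuron: inward synapses from its k nearest nodes
  d_out <- sqrt((x - x[output_id])^2 + (y - y[output_id])^2)
  d_out[output_id] <- Inf
  near_out <- order(d_out, seq_len(n_total))[seq_len(k)]
  pre <- c(pre, near_out)
  post <- c(post, rep(output_id, k))
  used_budget <- integer(n_total) # outgoing edges already assigned
  used_budget[near_out] <- 1L

  # input neurons: nearest hidden neighbours fill the remaining out-degree
  for (i in input_ids) {
    need <- k - used_budget[i]
    if (need <= 0) next
    d_i <- sqrt((x[hidden_ids] - x[i])^2 + (y[hidden_ids] - y[i])^2)
    if (length(hidden_ids) < need)
      .stopf("not enough hidden neurons to wire input neuron %d", i)
    nb <- hidden_ids[order(d_i, hidden_ids)][seq_len(need)]
    pre <- c(pre, rep(i, need))
    post <- c(post, nb)
  }

  # hidden neurons: distance-sampled wiring among the other hidden neurons
  pre_h <- vector("list", length(hidden_ids))
  post_h <- vector("list", length(hidden_ids))
  for (idx in seq_along(hidden_ids)) {
    i <- hidden_ids[idx]
    need <- k - used_budget[i]
    if (need <= 0) next
    cand <- hidden_ids[hidden_ids != i]
    if (length(cand) < need)
      .stopf("not enough candidate targets for hidden neuron %d", i)
    d_i <- sqrt((x[cand] - x[i])^2 + (y[cand] - y[i])^2)
    avail <- rep(TRUE, length(cand))
    chosen <- integer(need)
    draws <- rexp(need, rate = 1 / config$d0)
    for (m in seq_len(need)) {
      j <- .pick_nearest(d_i, avail, draws[m])
      avail[j] <- FALSE
      chosen[m] <- cand[j]
    }
    pre_h[[idx]] <- rep(i, need)
    post_h[[idx]] <- chosen
  }
  pre <- c(pre, unlist(pre_h))
  post <- c(post, unlist(post_h))

  synapses <- data.frame(pre = as.integer(pre), post = as.integer(post),
                         weight = NA_real_)
  new_network(neurons, synapses, input_ids, output_id, config$L, config)
}

# internal constructor shared by topology and fixtures
new_network <- function(neurons, synapses, input_ids, output_id, L,
                        config = NULL, subclass = NULL) {
  net <- structure(list(config = config, neurons = neurons,
                        synapses = synapses,
                        input_ids = as.integer(input_ids),
                        output_id = as.integer(output_id), L = L),
                   class = c(subclass, "spatplast_network"))
  validate_network(net)
  net
}

#' Validate the structural invariants of a network
#'
#' Checks: no self-loops, no duplicate directed edges, no synapses out of the
#' output neuron, none into an input neuron, non-negative weights (where set),
#' and positions inside the square.
#'
#' @param net a `spatplast_network`.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_network <- function(net) {
  s <- net$synapses
  if (any(s$pre == s$post)) .stopf("self-loop synapse found")
  if (anyDuplicated(s[c("pre", "post")]) > 0) .stopf("duplicate synapse found")
  if (any(s$pre == net$output_id)) .stopf("output neuron has outgoing synapses")
  if (any(s$post %in% net$input_ids)) .stopf("input neuron has incoming synapses")
  if (any(!is.na(s$weight) & s$weight < 0)) .stopf("negative synaptic weight")
  if (any(net$neurons$x < 0 | net$neurons$x > net$L |
          net$neurons$y < 0 | net$neurons$y > net$L))
    .stopf("neuron positions fall outside the square")
  invisible(net)
}

#' Set the initial synaptic weights
#'
#' Synapses leaving an input neuron start at 1.0; all other synapses start
#' at 0.1 (weak, sub-critical coupling to be raised by
#' [critical_initialization()]).
#'
#' @param net a wired `spatplast_network`.
#' @return the network with initial weights set.
#' @export
initialize_weights <- function(net) {
  stopifnot(inherits(net, "spatplast_network"))
  from_input <- net$synapses$pre %in% net$input_ids
  net$synapses$weight <- ifelse(from_input, 1.0, 0.1)
  net
}

#' Generate a spatially embedded random network
#'
#' Convenience wrapper: seeds the RNG (if `config$seed` is set), places the
#' neurons, wires the synapses and sets the initial weights.
#'
#' @param config a [topology_config()].
#' @return a ready-to-simulate `spatplast_network`.
#' @examples
#' net <- generate_network(topology_config(n_hidden = 100, d0 = 2, seed = 1))
#' net
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "spatplast_topology_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  initialize_weights(wire_network(place_neurons(config), config))
}

#' @export
print.spatplast_network <- function(x, ...) {
  n_inh <- sum(x$neurons$inhibitory)
  cat(sprintf(
    "spatplast network: %d neurons (%d input, %d hidden, 1 output), %d synapses\n",
    nrow(x$neurons), length(x$input_ids),
    sum(x$neurons$role == "hidden"), nrow(x$synapses)))
  cat(sprintf("  square side L = %.4g; inhibitory hidden neurons: %d\n",
              x$L, n_inh))
  if (!all(is.na(x$synapses$weight)))
    cat(sprintf("  weights: min %.4g, mean %.4g, max %.4g\n",
                min(x$synapses$weight), mean(x$synapses$weight),
                max(x$synapses$weight)))
  invisible(x)
}

# per-synapse Euclidean distance from the output neuron to the postsynaptic
# neuron (the adaptation signal is released at the output; a synapse is
# located at its postsynaptic neuron)
output_distances <- function(net) {
  o <- net$output_id
  nx <- net$neurons$x
  ny <- net$neurons$y
  j <- net$synapses$post
  sqrt((nx[j] - nx[o])^2 + (ny[j] - ny[o])^2)
}

# +1 for excitatory, -1 for inhibitory presynaptic neuron, per synapse
synapse_signs <- function(net) {
  ifelse(net$neurons$inhibitory[net$synapses$pre], -1, 1)
}

#' Realized connection distances
#'
#' Euclidean length of each synapse, optionally restricted to those whose
#' presynaptic neuron is hidden (the distance-sampled ones).
#'
#' @param net a `spatplast_network`.
#' @param hidden_only restrict to synapses originating from hidden neurons
#'   whose target is not the output neuron (the distance-sampled edges).
#' @return numeric vector of distances.
#' @export
connection_distances <- function(net, hidden_only = FALSE) {
  s <- net$synapses
  keep <- rep(TRUE, nrow(s))
  if (hidden_only) {
    hidden <- net$neurons$id[net$neurons$role == "hidden"]
    keep <- s$pre %in% hidden & s$post != net$output_id
  }
  nx <- net$neurons$x
  ny <- net$neurons$y
  sqrt((nx[s$pre[keep]] - nx[s$post[keep]])^2 +
       (ny[s$pre[keep]] - ny[s$post[keep]])^2)
}

#' Write / read a network as JSON
#'
#' Serializes neurons, synapses and the generating configuration to a JSON
#' document that [read_network()] restores exactly.
#'
#' @param net a `spatplast_network`.
#' @param path file path.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   the network.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "spatplast_network"))
  doc <- list(
    config = if (is.null(net$config)) NULL else unclass(net$config),
    L = net$L,
    input_ids = net$input_ids,
    output_id = net$output_id,
    neurons = net$neurons,
    synapses = net$synapses)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- doc$config
  if (!is.null(cfg) && length(cfg) > 0) {
    cfg <- structure(as.list(cfg), class = "spatplast_topology_config")
    cfg$n_hidden <- as.integer(cfg$n_hidden)
    cfg$out_degree <- as.integer(cfg$out_degree)
  } else cfg <- NULL
  neurons <- as.data.frame(doc$neurons)
  synapses <- as.data.frame(doc$synapses)
  synapses$weight <- as.numeric(synapses$weight)
  new_network(neurons, synapses, doc$input_ids, doc$output_id, doc$L, cfg)
}

#' Export a network to igraph / GraphML
#'
#' @param net a `spatplast_network`.
#' @param path GraphML output file (for `export_graphml`).
#' @return an `igraph` object, or (for `export_graphml`) `path` invisibly.
#' @export
as_igraph <- function(net) {
  if (!requireNamespace("igraph", quietly = TRUE))
    .stopf("the igraph package is required for graph export")
  v <- net$neurons
  names(v)[1] <- "name"
  igraph::graph_from_data_frame(net$synapses, directed = TRUE, vertices = v)
}

#' @rdname as_igraph
#' @export
export_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
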