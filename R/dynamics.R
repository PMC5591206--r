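#' Dynamics configuration
#'
#' Parameters of the discrete-time synchronous integrate-and-fire model. All
#' neurons with potential `v >= v_max` and no pending refractoriness fire
#' simultaneously; a firing neuron delivers `w * eta` (Heaviside activation)
#' or `w * eta * v` (linear activation, using the actual supra-threshold
#' potential at firing time) to each non-refractory postsynaptic neuron, then
#' resets to `v = 0`, loses `delta_eta` of its releasable transmitter
#' (floored at 0) and is refractory for `t_refr` steps, during which it can
#' neither receive nor send.
#'
#' @param v_max firing threshold (> 0, default 1.0).
#' @param delta_eta transmitter decrement per firing, in `(0, 1]` (default 0.2).
#' @param t_refr refractory duration in time steps (integer >= 0, default 1).
#' @param activation `"heaviside"` (fixed-amplitude spikes) or `"linear"`
#'   (amplitude proportional to the firing potential).
#' @param step_cap hard iteration limit; `NULL` resolves at run time to
#'   `10 * n_neurons * (1/delta_eta + 1)`, a generous bound on the number of
#'   steps transmitter depletion allows. Reaching it signals a bug.
#' @param refractory_blocks_same_step dialect flag: if `TRUE` (default) a
#'   neuron firing at step t also rejects deliveries arriving at step t from
#'   other neurons firing simultaneously; if `FALSE` such deliveries
#'   accumulate onto its freshly reset potential.
#' @return an object of class `spatplast_dynamics_config`.
#' @export
dynamics_config <- function(v_max = 1.0, delta_eta = 0.2, t_refr = 1,
                            activation = c("heaviside", "linear"),
                            step_cap = NULL,
                            refractory_blocks_same_step = TRUE) {
  activation <- match.arg(activation)
  if (!is.numeric(v_max) || v_max <= 0) .stopf("v_max must be > 0")
  if (!is.numeric(delta_eta) || delta_eta <= 0 || delta_eta > 1)
    .stopf("delta_eta must lie in (0, 1]")
  if (t_refr < 0 || t_refr != round(t_refr))
    .stopf("t_refr must be a non-negative integer")
  structure(list(v_max = v_max, delta_eta = delta_eta,
                 t_refr = as.integer(t_refr), activation = activation,
                 step_cap = step_cap,
                 refractory_blocks_same_step = refractory_blocks_same_step),
            class = "spatplast_dynamics_config")
}

.resolve_step_cap <- function(cfg, n_neurons) {
  if (!is.null(cfg$step_cap)) return(as.integer(cfg$step_cap))
  as.integer(ceiling(10 * n_neurons * (1 / cfg$delta_eta + 1)))
}

#' Reset the dynamical state of a network
#'
#' Restores `v = 0`, `eta = 1` and no refractoriness for every neuron, the
#' condition imposed before each input presentation.
#'
#' @param net a `spatplast_network`.
#' @param cfg a [dynamics_config()].
#' @return an object of class `spatplast_state` with fields `v`, `eta`,
#'   `refr` (per neuron) and step counter `t`.
#' @export
reset_state <- function(net, cfg = dynamics_config()) {
  n <- nrow(net$neurons)
  structure(list(v = numeric(n), eta = rep(1, n), refr = integer(n), t = 0L),
            class = "spatplast_state")
}

#' Apply an input pattern to a freshly reset state
#'
#' Input neurons carrying a 1 bit are set to the firing threshold so that
#' they fire at the first step; 0-bit inputs stay silent.
#'
#' @param state a [reset_state()] result.
#' @param pattern binary vector, one bit per input neuron.
#' @param net the network the state belongs to.
#' @param cfg a [dynamics_config()].
#' @return the updated state.
#' @export
apply_input <- function(state, pattern, net, cfg = dynamics_config()) {
  if (length(pattern) != length(net$input_ids))
    .stopf("pattern length %d does not match the %d input neurons",
           length(pattern), length(net$input_ids))
  if (!all(pattern %in% c(0, 1))) .stopf("pattern bits must be 0 or 1")
  state$v[net$input_ids[pattern == 1]] <- cfg$v_max
  state
}

#' Advance the network by one synchronous time step
#'
#' Pure-R reference implementation of the update used by the compiled engine:
#' identify firing neurons, deliver their (sign-carrying) weighted transmitter
#' to non-refractory targets, reset and deplete the firers, start their
#' refractory countdown and decrement the others'.
#'
#' @param state a `spatplast_state`.
#' @param net the network.
#' @param cfg a [dynamics_config()].
#' @return list with the updated `state`, the integer ids of `fired` neurons,
#'   and the indices of `activated` synapses (rows of `net$synapses`).
#' @export
step_network <- function(state, net, cfg = dynamics_config()) {
  fired <- which(state$refr == 0 & state$v >= cfg$v_max)
  if (length(fired) == 0)
    return(list(state = state, fired = integer(0), activated = integer(0)))
  state$t <- state$t + 1L
  fired_now <- logical(length(state$v))
  fired_now[fired] <- TRUE
  amp <- if (cfg$activation == "linear") state$eta[fired] * state$v[fired]
         else state$eta[fired]
  names(amp) <- fired
  state$v[fired] <- 0

  s <- net$synapses
  sgn <- synapse_signs(net)
  block_same <- isTRUE(cfg$refractory_blocks_same_step) && cfg$t_refr > 0
  out_slots <- which(s$pre %in% fired)
  activated <- integer(0)
  for (k in seq_along(fired)) {
    i <- fired[k]
    slots <- out_slots[s$pre[out_slots] == i]
    for (sl in slots) {
      j <- s$post[sl]
      if (state$refr[j] > 0 || (block_same && fired_now[j])) next
      state$v[j] <- state$v[j] + sgn[sl] * s$weight[sl] * amp[k]
      activated <- c(activated, sl)
    }
  }
  state$eta[fired] <- pmax(0, state$eta[fired] - cfg$delta_eta)
  countdown <- state$refr > 0 & !fired_now
  state$refr[countdown] <- state$refr[countdown] - 1L
  state$refr[fired] <- cfg$t_refr
  list(state = state, fired = fired, activated = sort(activated))
}

#' Simulate one input presentation
#'
#' Resets the network state, applies the pattern and iterates the synchronous
#' update until no neuron is eligible to fire. The trial is guaranteed to
#' terminate: every firing consumes releasable transmitter, so the total
#' activity a network can produce is finite.
#'
#' @param net a `spatplast_network` with weights set.
#' @param pattern binary input vector (one bit per input neuron).
#' @param cfg a [dynamics_config()].
#' @param record_firings if `TRUE`, keep the full `(time, neuron)` firing log.
#' @param engine `"cpp"` (compiled, default) or `"r"` (the [step_network()]
#'   reference loop; slow, for instrumentation and cross-checking).
#' @return an object of class `spatplast_trial`: list with `output_fired`,
#'   `output_voltage_changed` (whether any incoming synapse of the output
#'   neuron was activated), per-synapse activation counts `n_act`, the trial
#'   `duration` in steps, and optionally a `firings` data frame.
#' @examples
#' net <- chain_fixture(length = 1, weight = 1)
#' run_trial(net, 1, dynamics_config(t_refr = 1))
#' @export
run_trial <- function(net, pattern, cfg = dynamics_config(),
                      record_firings = FALSE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (length(pattern) != length(net$input_ids))
    .stopf("pattern length %d does not match the %d input neurons",
           length(pattern), length(net$input_ids))
  if (!all(pattern %in% c(0, 1))) .stopf("pattern bits must be 0 or 1")
  if (any(is.na(net$synapses$weight)))
    .stopf("network weights are unset; call initialize_weights() first")
  n <- nrow(net$neurons)
  cap <- .resolve_step_cap(cfg, n)
  if (engine == "cpp") {
    res <- cpp_run_trial(
      n, net$synapses$pre, net$synapses$post, net$synapses$weight,
      synapse_signs(net), net$output_id,
      net$input_ids[pattern == 1], cfg$v_max, cfg$delta_eta, cfg$t_refr,
      cfg$activation == "linear", isTRUE(cfg$refractory_blocks_same_step),
      cap, record_firings)
    firings <- if (record_firings)
      data.frame(time = res$firings_time, neuron = res$firings_neuron)
    else NULL
    return(structure(list(output_fired = res$output_fired,
                          output_voltage_changed = res$output_voltage_changed,
                          n_act = res$n_act, duration = res$duration,
                          firings = firings),
                     class = "spatplast_trial"))
  }
  # reference engine
  state <- apply_input(reset_state(net, cfg), pattern, net, cfg)
  n_act <- integer(nrow(net$synapses))
  out_fired <- FALSE
  v_changed <- FALSE
  duration <- 0L
  log_t <- integer(0); log_id <- integer(0)
  repeat {
    stepped <- step_network(state, net, cfg)
    if (length(stepped$fired) == 0) {
      # silent step: quiescent unless a refractory neuron still holds a
      # supra-threshold potential (possible under the open same-step
      # dialect); then time simply passes until its window expires
      if (!any(state$refr > 0 & state$v >= cfg$v_max)) break
      ticking <- state$refr > 0
      state$refr[ticking] <- state$refr[ticking] - 1L
      state$t <- state$t + 1L
      if (state$t > cap) .stopf("simulation exceeded step cap (%d)", cap)
      next
    }
    state <- stepped$state
    duration <- state$t
    if (duration > cap)
      .stopf("simulation exceeded step cap (%d)", cap)
    n_act[stepped$activated] <- n_act[stepped$activated] + 1L
    if (any(net$synapses$post[stepped$activated] == net$output_id))
      v_changed <- TRUE
    if (net$output_id %in% stepped$fired) out_fired <- TRUE
    if (record_firings) {
      log_t <- c(log_t, rep(duration, length(stepped$fired)))
      log_id <- c(log_id, stepped$fired)
    }
  }
  firings <- if (record_firings) data.frame(time = log_t, neuron = log_id)
             else NULL
  structure(list(output_fired = out_fired, output_voltage_changed = v_changed,
                 n_act = n_act, duration = duration, firings = firings),
            class = "spatplast_trial")
}

#' @export
print.spatplast_trial <- function(x, ...) {
  cat(sprintf(
    "trial: output %s, %d steps, %d synapse activations%s\n",
    if (x$output_fired) "fired" else "silent", x$duration, sum(x$n_act),
    if (x$output_voltage_changed) "" else " (no signal reached the output)"))
  invisible(x)
}

#' Write a trial firing log to CSV
#'
#' @param trial a [run_trial()] result obtained with `record_firings = TRUE`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_firings <- function(trial, path) {
  if (is.null(trial$firings))
    .stopf("trial was run without record_firings = TRUE")
  write.csv(trial$firings, path, row.names = FALSE)
  invisible(path)
}
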