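# The 15 four-input Boolean patterns the networks are trained on, in fixed
# column order. Rows: input1..input4, output.
.rule_table <- rbind(
  input1 = c(1, 0, 1, 0, 0, 0, 1, 1, 1, 1, 0, 0, 1, 1, 0),
  input2 = c(0, 1, 1, 0, 0, 0, 1, 0, 1, 0, 1, 1, 1, 0, 1),
  input3 = c(0, 0, 0, 1, 0, 1, 1, 1, 1, 0, 1, 0, 0, 1, 1),
  input4 = c(0, 0, 0, 0, 1, 1, 1, 0, 0, 1, 0, 1, 1, 1, 1),
  output = c(1, 1, 0, 1, 1, 0, 0, 1, 0, 1, 0, 1, 0, 1, 0))

#' The embedded Boolean rule table
#'
#' The 15 four-input/one-output pattern pairs the networks learn, as a data
#' frame with one pattern per row.
#'
#' @return data frame with columns `input1`..`input4`, `output`.
#' @export
rule_table <- function() {
  as.data.frame(t(.rule_table))
}

#' Construct a Boolean rule
#'
#' @param patterns integer matrix of 0/1 bits, one pattern per row, one
#'   column per input neuron.
#' @param targets integer vector of 0/1 target output bits, one per pattern.
#' @param name label for the rule.
#' @return an object of class `spatplast_rule`.
#' @export
new_rule <- function(patterns, targets, name = "custom") {
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "integer"
  targets <- as.integer(targets)
  if (nrow(patterns) != length(targets))
    .stopf("patterns and targets disagree in length")
  if (nrow(patterns) < 1) .stopf("a rule needs at least one pattern")
  if (!all(patterns %in% c(0L, 1L)) || !all(targets %in% c(0L, 1L)))
    .stopf("rule entries must be 0/1 bits")
  structure(list(patterns = patterns, targets = targets, name = name),
            class = "spatplast_rule")
}

#' Load a Boolean rule
#'
#' `selector` is either a prefix of the embedded table (`"first3"`,
#' `"first10"`, ..., `"first15"`, or the alias `"all15"`) or the path of a
#' plain-text rule file with one pattern per line in the form
#' `"b b b b -> b"` (`#` comments and blank lines ignored).
#'
#' @param selector character selector or file path.
#' @return an object of class `spatplast_rule`.
#' @examples
#' load_rule("first10")
#' @export
load_rule <- function(selector) {
  if (inherits(selector, "spatplast_rule")) return(selector)
  stopifnot(is.character(selector), length(selector) == 1)
  m <- regmatches(selector, regexec("^(first|all)([0-9]+)$", selector))[[1]]
  if (length(m) == 3) {
    k <- as.integer(m[3])
    if (k < 1 || k > ncol(.rule_table))
      .stopf("the embedded table has %d patterns; cannot take %d",
             ncol(.rule_table), k)
    if (m[2] == "all" && k != ncol(.rule_table))
      .stopf("unknown rule selector '%s'", selector)
    return(new_rule(t(.rule_table[1:4, seq_len(k), drop = FALSE]),
                    .rule_table[5, seq_len(k)],
                    name = paste0("table:first", k)))
  }
  if (!file.exists(selector)) .stopf("unknown rule selector '%s'", selector)
  lines <- trimws(readLines(selector))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) .stopf("rule file '%s' contains no patterns", selector)
  parts <- strsplit(lines, "->", fixed = TRUE)
  if (any(lengths(parts) != 2))
    .stopf("malformed rule line (expected 'b b b b -> b')")
  inputs <- lapply(parts, function(p) scan(text = p[1], quiet = TRUE))
  targets <- vapply(parts, function(p) scan(text = p[2], quiet = TRUE), 0)
  if (length(unique(lengths(inputs))) != 1)
    .stopf("rule patterns have inconsistent input widths")
  new_rule(do.call(rbind, inputs), targets, name = basename(selector))
}

#' @export
print.spatplast_rule <- function(x, ...) {
  cat(sprintf("rule '%s': %d patterns of %d inputs\n",
              x$name, nrow(x$patterns), ncol(x$patterns)))
  invisible(x)
}

#' Train a network on a Boolean rule
#'
#' Presents the rule's patterns cyclically, resetting the network state
#' before each presentation. A wrong answer triggers one learning step:
#' [adapt()] in the `strengthen` direction if the target was 1 but the output
#' stayed silent, `weaken` if the target was 0 but the output fired, or --
#' when the trial left the output neuron's voltage unchanged so that the
#' network could not answer at all -- a global [boost_all()] with
#' `boost_factor`. Training succeeds when a full cycle of consecutive
#' presentations is answered correctly, and fails when `t_max` learning
#' steps have been spent.
#'
#' @param net a `spatplast_network`, normally after
#'   [critical_initialization()].
#' @param rule a [load_rule()] result (or selector passed through it).
#' @param dyn_cfg a [dynamics_config()].
#' @param learn_cfg a [learning_config()].
#' @param t_max maximal number of learning steps.
#' @param record_history if `TRUE`, keep a per-learning-step log.
#' @return an object of class `spatplast_training`: list with `learned`,
#'   `learning_steps`, `boosts` (weak-activity boosts, included in the step
#'   count), the trained `net`, and optionally a `history` data frame with
#'   columns `pattern`, `produced`, `target`, `event`.
#' @export
train <- function(net, rule, dyn_cfg = dynamics_config(), learn_cfg,
                  t_max = 10000, record_history = FALSE) {
  rule <- load_rule(rule)
  stopifnot(inherits(learn_cfg, "spatplast_learning_config"))
  if (ncol(rule$patterns) != length(net$input_ids))
    .stopf("rule input width does not match the network")
  if (t_max < 0) .stopf("t_max must be >= 0")
  n <- nrow(net$neurons)
  kern <- kernel_factor(output_distances(net), learn_cfg)
  res <- cpp_train(
    n, net$synapses$pre, net$synapses$post, net$synapses$weight,
    synapse_signs(net), net$output_id,
    rule$patterns, rule$targets, net$input_ids, kern,
    learn_cfg$alpha, learn_cfg$omega_max, learn_cfg$boost_factor,
    as.integer(t_max),
    dyn_cfg$v_max, dyn_cfg$delta_eta, dyn_cfg$t_refr,
    dyn_cfg$activation == "linear",
    isTRUE(dyn_cfg$refractory_blocks_same_step),
    .resolve_step_cap(dyn_cfg, n), record_history)
  net$synapses$weight <- res$weight
  history <- NULL
  if (record_history)
    history <- data.frame(pattern = res$history_pattern,
                          produced = res$history_produced,
                          target = res$history_target,
                          event = c("strengthen", "weaken",
                                    "boost")[res$history_event + 1L])
  structure(list(learned = res$learned, learning_steps = res$learning_steps,
                 boosts = res$boosts, net = net, history = history,
                 rule = rule$name),
            class = "spatplast_training")
}

#' @export
print.spatplast_training <- function(x, ...) {
  cat(sprintf("training on '%s': %s after %d learning steps (%d boosts)\n",
              x$rule, if (x$learned) "learned" else "not learned",
              x$learning_steps, x$boosts))
  invisible(x)
}

#' Count the errors a network makes on a rule
#'
#' Read-only pass: presents every pattern once (state reset in between, no
#' adaptation) and counts the mismatches between produced and target bits.
#'
#' @param net a `spatplast_network`.
#' @param rule a rule or selector.
#' @param dyn_cfg a [dynamics_config()].
#' @return integer error count.
#' @export
evaluate <- function(net, rule, dyn_cfg = dynamics_config()) {
  rule <- load_rule(rule)
  errs <- 0L
  for (p in seq_len(nrow(rule$patterns))) {
    tr <- run_trial(net, rule$patterns[p, ], dyn_cfg)
    produced <- as.integer(tr$output_fired)
    if (produced != rule$targets[p]) errs <- errs + 1L
  }
  errs
}
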