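#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return named numeric vector `c(low, high)`.
#' @export
wilson_interval <- function(successes, n, conf = 0.95) {
  if (n < 1 || successes < 0 || successes > n)
    .stopf("need 0 <= successes <= n with n >= 1")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Ensemble success rate for one parameter combination
#'
#' Generates `ensemble_size` independent random networks (replicate `i` uses
#' seed `base_seed + i`), runs [critical_initialization()] followed by
#' [train()] on each, and reports the fraction `s` of networks that learn the
#' whole rule within `t_max` learning steps, with a 95% Wilson confidence
#' interval. Replicate-level errors are caught, counted as failures and
#' tallied in `n_error_runs`.
#'
#' @param r0 learning length.
#' @param n_hidden,d0,p_inh,out_degree,density network parameters, see
#'   [topology_config()].
#' @param t_refr,activation dynamics parameters, see [dynamics_config()].
#' @param kernel,alpha,omega_max adaptation parameters, see
#'   [learning_config()].
#' @param rule rule selector, see [load_rule()].
#' @param t_max maximal learning steps per network.
#' @param ensemble_size networks per estimate (desk-scale default 20).
#' @param base_seed replicate `i` is generated with seed `base_seed + i`.
#' @param conf confidence level of the interval.
#' @return one-row data frame: the parameters plus `successes`,
#'   `ensemble_size`, `s`, `ci_low`, `ci_high`, `mean_steps_success`,
#'   `r0_over_L` and `n_error_runs`.
#' @export
success_rate <- function(r0, n_hidden = 1000, d0 = 2, p_inh = 0,
                         out_degree = 10, density = 1, t_refr = 1,
                         activation = "heaviside", kernel = "exponential",
                         alpha = 0.001, omega_max = 2, rule = "first10",
                         t_max = 10000, ensemble_size = 20, base_seed = 0,
                         conf = 0.95) {
  if (ensemble_size < 1) .stopf("ensemble_size must be >= 1")
  rule_obj <- load_rule(rule)
  learn_cfg <- learning_config(r0 = r0, alpha = alpha, kernel = kernel,
                               omega_max = omega_max)
  dyn_cfg <- dynamics_config(t_refr = t_refr, activation = activation)
  successes <- 0L
  n_error_runs <- 0L
  steps_success <- numeric(0)
  for (i in seq_len(ensemble_size)) {
    res <- tryCatch({
      cfg <- topology_config(n_hidden = n_hidden, d0 = d0, p_inh = p_inh,
                             out_degree = out_degree, density = density,
                             seed = base_seed + i)
      net <- generate_network(cfg)
      init <- critical_initialization(net, rule_obj, dyn_cfg, learn_cfg)
      train(init$net, rule_obj, dyn_cfg, learn_cfg, t_max = t_max)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_error_runs <- n_error_runs + 1L
      next
    }
    if (res$learned) {
      successes <- successes + 1L
      steps_success <- c(steps_success, res$learning_steps)
    }
  }
  ci <- wilson_interval(successes, ensemble_size, conf)
  L <- sqrt(n_hidden / density)
  data.frame(r0 = r0, n_hidden = n_hidden, d0 = d0, p_inh = p_inh,
             t_refr = t_refr, activation = activation, kernel = kernel,
             rule = rule_obj$name, t_max = t_max,
             ensemble_size = ensemble_size, successes = successes,
             s = successes / ensemble_size,
             ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
             mean_steps_success = if (length(steps_success))
               mean(steps_success) else NA_real_,
             r0_over_L = r0 / L, n_error_runs = n_error_runs,
             stringsAsFactors = FALSE)
}

.sweep_keys <- c("r0", "n_hidden", "d0", "p_inh", "t_refr", "activation",
                 "kernel", "rule", "t_max", "out_degree", "density",
                 "alpha", "omega_max")

#' Run a success-rate parameter sweep
#'
#' Evaluates [success_rate()] on the Cartesian product of the supplied
#' parameter value lists. Completed rows can be streamed to a CSV file,
#' which doubles as a checkpoint: on rerun, cells already present in the
#' file are skipped and their stored rows reused.
#'
#' @param grid named list mapping parameter names (any of
#'   `r0, n_hidden, d0, p_inh, t_refr, activation, kernel, rule, t_max,
#'   out_degree, density, alpha, omega_max`) to value vectors.
#' @param ensemble_size networks per cell.
#' @param base_seed shared base seed; every cell uses replicate seeds
#'   `base_seed + 1 .. base_seed + ensemble_size`, so cells differing only in
#'   method parameters are paired on the same networks.
#' @param out_csv optional checkpoint/result CSV path.
#' @param conf confidence level.
#' @return data frame with one row per grid cell.
#' @export
run_sweep <- function(grid, ensemble_size = 20, base_seed = 0,
                      out_csv = NULL, conf = 0.95) {
  stopifnot(is.list(grid), length(grid) > 0, !is.null(names(grid)))
  unknown <- setdiff(names(grid), .sweep_keys)
  if (length(unknown))
    .stopf("unrecognized sweep parameter(s): %s",
           paste(unknown, collapse = ", "))
  cells <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  done <- NULL
  if (!is.null(out_csv) && file.exists(out_csv))
    done <- read.csv(out_csv, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    args <- as.list(cells[ci, , drop = FALSE])
    if (!is.null(done)) {
      key_cols <- intersect(names(args), names(done))
      hit <- rep(TRUE, nrow(done))
      for (kc in key_cols) hit <- hit & done[[kc]] == args[[kc]]
      if (any(hit)) {
        rows[[ci]] <- done[which(hit)[1], , drop = FALSE]
        next
      }
    }
    args$ensemble_size <- ensemble_size
    args$base_seed <- base_seed
    args$conf <- conf
    row <- do.call(success_rate, args)
    rows[[ci]] <- row
    if (!is.null(out_csv)) {
      first <- !file.exists(out_csv)
      suppressWarnings(
        write.table(row, out_csv, sep = ",", append = !first,
                    col.names = first, row.names = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a success-rate sweep
#'
#' Success rate with its confidence interval against a (log-scaled) sweep
#' axis, one curve per value of an optional grouping parameter -- the layout
#' used throughout for learning-length sweeps.
#'
#' @param result a [run_sweep()] (or row-bound [success_rate()]) data frame.
#' @param x,y column names for the axes (defaults `r0_over_L` and `s`).
#' @param colour optional column name used to group/colour curves.
#' @param logx log-scale the x axis (default `TRUE`).
#' @param file optional output path (any device `ggplot2::ggsave()`
#'   understands).
#' @return the ggplot object, invisibly if written to file.
#' @export
plot_sweep <- function(result, x = "r0_over_L", y = "s", colour = NULL,
                       logx = TRUE, file = NULL) {
  if (!is.data.frame(result) || nrow(result) == 0)
    .stopf("result must be a non-empty data frame")
  needed <- c(x, y, "ci_low", "ci_high", colour)
  missing_cols <- setdiff(needed, names(result))
  if (length(missing_cols))
    .stopf("unknown axis column(s): %s", paste(missing_cols, collapse = ", "))
  aes_args <- list(x = as.name(x), y = as.name(y))
  if (!is.null(colour)) {
    result[[colour]] <- factor(result[[colour]])
    aes_args$colour <- as.name(colour)
    aes_args$group <- as.name(colour)
  }
  p <- ggplot2::ggplot(result, do.call(ggplot2::aes, aes_args)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::labs(x = x, y = "success rate s") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
  if (logx) p <- p + ggplot2::scale_x_log10()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 4)
    return(invisible(p))
  }
  p
}
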