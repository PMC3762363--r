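#' @export
print.maxent <- function(x, ...) {
  kind <- if (x$epsilon > 0) sprintf("L1-penalized (epsilon = %.3g)", x$epsilon)
          else "unpenalized"
  cat(sprintf("Maximum entropy model, order %d: %d animals x %d zones, %s\n",
              x$order, x$n_animals, x$n_zones, kind))
  cat(sprintf("  entropy %.4f bits; log2 partition %.4f; %s (worst marginal residual %.2e)\n",
              entropy(x$table), x$log_partition,
              if (x$converged) "converged" else "NOT converged", x$residual))
  invisible(x)
}

#' @describeIn maxent Summary with per-order parameter counts and sparsity.
#' @param object,... Method arguments.
#' @export
summary.maxent <- function(object, ...) {
  ords <- lengths(lapply(names(object$params), key_subset))
  by_order <- lapply(sort(unique(ords)), function(k) {
    v <- unlist(object$params[ords == k], use.names = FALSE)
    data.frame(order = k, n_params = length(v), n_zero = sum(v == 0),
               mean_nonzero = if (any(v != 0)) mean(v[v != 0]) else NA_real_)
  })
  out <- list(model = object, params_by_order = do.call(rbind, by_order),
              entropy = entropy(object$table),
              multi_information = multi_information(object$table))
  class(out) <- "summary.maxent"
  out
}

#' @export
print.summary.maxent <- function(x, ...) {
  print(x$model)
  cat(sprintf("  multi-information of model: %.4f bits\n", x$multi_information))
  cat("  parameters by interaction order:\n")
  print(x$params_by_order, row.names = FALSE)
  invisible(x)
}

#' Model parameters
#'
#' `gauge = "fitted"` returns the parameter blocks exactly as the optimizer
#' produced them (for L1 fits these carry the exact zeros and the penalty's
#' implicit gauge). `gauge = "zero.sum"` returns the unique zero-sum-gauge
#' representation computed from the fitted table (see [zero_sum_gauge()]),
#' which is the form in which interaction signs and strengths are comparable
#' across models.
#'
#' @param object A [maxent()] model.
#' @param gauge `"fitted"` or `"zero.sum"`.
#' @param ... Unused.
#' @return Named list of parameter arrays keyed by animal subset.
#' @export
coef.maxent <- function(object, gauge = c("fitted", "zero.sum"), ...) {
  gauge <- match.arg(gauge)
  if (gauge == "fitted") return(object$params)
  zero_sum_gauge(object$table, max_order = object$order)
}

#' Model probabilities of configurations
#'
#' Without `newdata`, returns the model's full joint table. With `newdata` (a
#' [config_series()] or an integer matrix of configurations), returns the
#' model probability of each row.
#'
#' @param object A [maxent()] model.
#' @param newdata Optional configurations.
#' @param ... Unused.
#' @return A [joint_distribution()] or a numeric vector.
#' @export
predict.maxent <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$table)
  states <- if (inherits(newdata, "config_series")) newdata$states else as.matrix(newdata)
  if (ncol(states) != object$n_animals)
    abort_argument("newdata must have one column per animal")
  as.vector(unclass(object$table))[config_linear_index(states, object$n_zones)]
}

#' Draw independent configuration samples from a model
#'
#' Inverse-CDF sampling over the exact model table: i.i.d. draws, no temporal
#' structure. For series with realistic temporal persistence see
#' [sample_markov_series()].
#'
#' @param object A [maxent()] model.
#' @param nsim Number of time bins to draw.
#' @param seed Integer seed (required for reproducibility; the caller's RNG
#'   state is left untouched).
#' @param bin_duration Bin duration of the returned series, seconds.
#' @param ... Unused.
#' @return A [config_series()].
#' @export
simulate.maxent <- function(object, nsim = 1L, seed = 1L, bin_duration = 0.24,
                            ...) {
  if (nsim < 1) abort_argument("nsim must be >= 1")
  p <- as.vector(unclass(object$table))
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  idx <- sample.int(length(p), nsim, replace = TRUE, prob = p)
  states <- arrayInd(idx, .dim = rep(object$n_zones, object$n_animals))
  config_series(states, bin_duration = bin_duration, n_zones = object$n_zones,
                animal_ids = attr(object$table, "animal_ids"),
                legend = attr(object$table, "legend"))
}

#' @rdname simulate.maxent
#' @param model A [maxent()] model.
#' @param n Number of draws.
#' @export
sample_configurations <- function(model, n, seed = 1L, bin_duration = 0.24) {
  simulate(model, nsim = n, seed = seed, bin_duration = bin_duration)
}

#' Marginal-constraint residuals of a fitted model
#'
#' The difference between each model marginal and its (floored) constraint
#' table; for penalized fits these quantify how soft the constraints became.
#'
#' @param object A [maxent()] model fitted from data (not a constructed one).
#' @param ... Unused.
#' @return Named list of residual arrays, or `NULL` if the model carries no
#'   constraints.
#' @export
residuals.maxent <- function(object, ...) {
  if (is.null(object$constraints)) return(NULL)
  subs <- lapply(names(object$params), key_subset)
  margs <- model_marginals(unclass(object$table), subs)
  out <- Map(function(m, t) m - t, margs, object$constraints)
  names(out) <- names(object$params)
  out
}

#' Model-versus-data scatter with a confidence funnel
#'
#' Plots each configuration's model probability against its probability in a
#' test sample, on log-log axes, with the per-state 95% multinomial (Wilson
#' score) interval shown as a grey funnel -- the standard visual check of how
#' well an interaction order explains held-out group configurations.
#'
#' @param x A [maxent()] model.
#' @param test A [joint_distribution()] with `sample_count > 0` (held-out
#'   empirical distribution). Defaults to the model's own table check being
#'   impossible, so it must be supplied.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.maxent <- function(x, test, ...) {
  ev <- evaluate_model(x, test)
  tab <- ev$states
  lim <- range(c(tab$p_test[tab$p_test > 0], tab$p_model[tab$p_model > 0]))
  graphics::plot(tab$p_test, tab$p_model, log = "xy", xlim = lim, ylim = lim,
                 xlab = "empirical probability (test)",
                 ylab = "model probability",
                 pch = 16, cex = 0.5,
                 col = ifelse(tab$in_funnel, "grey40", "firebrick"), ...)
  ord <- order(tab$p_test)
  graphics::lines(tab$p_test[ord], tab$funnel_lo[ord], col = "grey70")
  graphics::lines(tab$p_test[ord], tab$funnel_hi[ord], col = "grey70")
  graphics::abline(0, 1, col = "grey50", lty = 2, untf = TRUE)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("order %d: JS = %.4f, funnel coverage %.2f",
                                    x$order, ev$js_divergence, ev$funnel_coverage))
  invisible(ev)
}
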