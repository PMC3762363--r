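#' Random half/half train-test split of a series
#'
#' Partitions the time bins at random into two disjoint, exhaustive halves
#' (sizes `ceiling(T/2)` and `floor(T/2)`), for cross-validated model
#' evaluation. The split treats bins as exchangeable, matching the i.i.d.
#' plug-in estimators used throughout.
#'
#' @param series A [config_series()].
#' @param seed Integer seed; the same seed always yields the same split.
#' @return A list with elements `train` and `test`, both [config_series()].
#' @export
split_train_test <- function(series, seed = 1L) {
  stopifnot(inherits(series, "config_series"))
  T_ <- nrow(series$states)
  if (T_ < 2L) abort_argument("need at least 2 time bins to split")
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  n_train <- ceiling(T_ / 2)
  idx <- sample.int(T_, n_train)
  make <- function(rows) config_series(series$states[rows, , drop = FALSE],
                                       bin_duration = series$bin_duration,
                                       n_zones = series$n_zones,
                                       animal_ids = series$animal_ids,
                                       legend = series$legend)
  list(train = make(sort(idx)), test = make(sort(setdiff(seq_len(T_), idx))))
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  cbind(lo = pmax(center - half, 0), hi = pmin(center + half, 1))
}

#' Evaluate a model against held-out data
#'
#' Compares the model's joint table with an empirical (test) distribution:
#' per-configuration probability pairs, the base-2 Jensen-Shannon divergence,
#' and the fraction of observed configurations whose model probability lies
#' inside the per-state 95% Wilson score interval around the empirical
#' estimate at the test sample size (the "confidence funnel").
#'
#' @param model A [maxent()] model.
#' @param test A [joint_distribution()] with `sample_count > 0`, typically
#'   [empirical_distribution()] of the held-out half.
#' @param conf Funnel confidence level.
#' @return An object of class `"model_evaluation"`: list with `js_divergence`
#'   (in [0, 1]), `funnel_coverage`, `n_test`, and `states`, a data frame over
#'   configurations observed in the test set.
#' @export
evaluate_model <- function(model, test, conf = 0.95) {
  stopifnot(inherits(model, "maxent"))
  test <- as_joint_dist(test)
  if (sample_count(test) <= 0)
    abort_argument("test distribution must carry a positive sample_count")
  if (n_animals(test) != model$n_animals || n_zones(test) != model$n_zones)
    abort_argument("test distribution and model live on different state spaces")
  p_test <- as.vector(unclass(test))
  p_model <- as.vector(unclass(model$table))
  n <- sample_count(test)
  obs <- which(p_test > 0)
  ci <- wilson_interval(round(p_test[obs] * n), n, conf)
  in_funnel <- p_model[obs] >= ci[, "lo"] & p_model[obs] <= ci[, "hi"]
  states <- data.frame(state = obs, p_test = p_test[obs], p_model = p_model[obs],
                       funnel_lo = ci[, "lo"], funnel_hi = ci[, "hi"],
                       in_funnel = in_funnel)
  structure(list(js_divergence = js_divergence(test, model$table),
                 funnel_coverage = mean(in_funnel),
                 n_test = n, order = model$order, states = states),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("Model evaluation (order %d) on %d held-out bins:\n", x$order, x$n_test))
  cat(sprintf("  Jensen-Shannon divergence: %.5f\n  95%% funnel coverage: %.3f over %d observed states\n",
              x$js_divergence, x$funnel_coverage, nrow(x$states)))
  invisible(x)
}

#' Decompose group correlation into per-order interaction contributions
#'
#' Fits the full hierarchy of maximum entropy models \eqn{p^{(1)}, \dots,
#' p^{(N)}}, each constrained by all empirical marginals up to its order. The
#' model entropies decrease monotonically to the empirical entropy,
#' \deqn{H[p^{(1)}] \ge H[p^{(2)}] \ge \dots \ge H[p^{(N)}] = H,}
#' and the total correlation (multi-information)
#' \eqn{I_N = \sum_j H(x_j) - H} splits exactly into per-order contributions
#' \eqn{I_{(k)} = H[p^{(k-1)}] - H[p^{(k)}]}, the part of the group's
#' correlation attributable to order-k interactions.
#'
#' @param x A [config_series()] or [joint_distribution()].
#' @param max_order Highest order to fit (default N). Orders above `max_order`
#'   are not decomposed; the chain then ends at `H[p^(max_order)]`.
#' @param epsilon L1 penalty passed to each fit (0 = hard constraints).
#' @param control A [maxent_control()].
#' @param keep_models Keep the fitted models in the result?
#' @return An object of class `"maxent_decomp"`: list with `entropies` (named
#'   vector, orders 1..N), `multi_information`, `contributions` (I_(2)..I_(N))
#'   and `fractions` (contributions / I_N).
#' @examples
#' s <- config_series(cbind(rep(1:2, 50), rep(1:2, 50)), n_zones = 2)
#' decompose(s)
#' @export
decompose <- function(x, max_order = NULL, epsilon = 0,
                      control = maxent_control(), keep_models = FALSE) {
  dist <- as_joint_dist(x)
  N <- n_animals(dist)
  max_order <- as.integer(max_order %||% N)
  if (max_order < 1 || max_order > N)
    abort_argument(sprintf("max_order must be in 1..%d", N))
  models <- vector("list", max_order)
  entropies <- numeric(max_order)
  for (k in seq_len(max_order)) {
    models[[k]] <- maxent(dist, order = k, epsilon = if (k == N) 0 else epsilon,
                          control = control)
    entropies[k] <- entropy(models[[k]]$table)
  }
  names(entropies) <- paste0("p", seq_len(max_order))
  i_n <- multi_information(dist)
  contributions <- if (max_order >= 2L) -diff(entropies) else numeric(0)
  if (length(contributions))
    names(contributions) <- paste0("I", seq(2L, max_order))
  fractions <- if (i_n > 0) contributions / i_n else contributions * NA_real_
  structure(list(entropies = entropies,
                 empirical_entropy = entropy(dist),
                 multi_information = i_n,
                 contributions = contributions,
                 fractions = fractions,
                 n_animals = N, n_zones = n_zones(dist),
                 sample_count = sample_count(dist),
                 max_order = max_order,
                 models = if (keep_models) models else NULL),
            class = "maxent_decomp")
}

#' @export
print.maxent_decomp <- function(x, ...) {
  cat(sprintf("Correlation-order decomposition (%d animals x %d zones)\n",
              x$n_animals, x$n_zones))
  cat(sprintf("  multi-information I_N = %.4f bits\n", x$multi_information))
  cat("  model entropies (bits):", paste(sprintf("%s=%.4f", names(x$entropies),
                                                 x$entropies), collapse = "  "), "\n")
  if (length(x$contributions)) {
    cat("  per-order contributions (bits):\n")
    for (i in seq_along(x$contributions)) {
      cat(sprintf("    %s = %.4f  (%.1f%% of I_N)\n", names(x$contributions)[i],
                  x$contributions[i], 100 * x$fractions[i]))
    }
  }
  invisible(x)
}
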