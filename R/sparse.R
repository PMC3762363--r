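#' Sparsity / accuracy tradeoff of the L1-penalized model
#'
#' Fits the penalized model for each penalty weight in `epsilons` and records
#' (i) the Jensen-Shannon divergence between the penalized and the
#' unpenalized fit of the same order and (ii) the fraction of exactly-zero
#' parameters per interaction order. Both are non-decreasing in the penalty
#' (up to optimizer tolerance); the curve is the standard way to pick a
#' penalty that trades a small loss of accuracy for a much sparser
#' interaction map.
#'
#' @param x Data accepted by [maxent()].
#' @param order Model order.
#' @param epsilons Ascending vector of nonnegative penalty weights.
#' @param control A [maxent_control()].
#' @return A data frame of class `"sparsity_curve"` with columns `epsilon`,
#'   `js_to_unpenalized`, and `frac_zero_order<k>` for each order.
#' @export
sparsity_curve <- function(x, order = 3L, epsilons = 2^seq(-20, -4, by = 2),
                           control = maxent_control()) {
  if (is.unsorted(epsilons)) abort_argument("epsilons must be sorted ascending")
  if (any(epsilons < 0)) abort_argument("epsilons must be nonnegative")
  marg <- if (inherits(x, "marginal_set")) x else marginal_set(as_joint_dist(x), order)
  ref <- maxent(marg, order = order, control = control)
  rows <- lapply(epsilons, function(eps) {
    fit <- if (eps == 0) ref else maxent(marg, order = order, epsilon = eps,
                                         control = control)
    ords <- lengths(lapply(names(fit$params), key_subset))
    fz <- vapply(seq_len(order), function(k) {
      v <- unlist(fit$params[ords == k], use.names = FALSE)
      mean(v == 0)
    }, numeric(1))
    out <- data.frame(epsilon = eps,
                      js_to_unpenalized = js_divergence(fit$table, ref$table))
    out[paste0("frac_zero_order", seq_len(order))] <- as.list(fz)
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sparsity_curve", class(out))
  out
}

#' Extract the sparse functional interaction map of a model
#'
#' Lists the nonzero interaction parameters (orders >= 2) of a fitted model as
#' a ranked table: which animal subset, at which zone combination, with what
#' signed strength. Positive entries mark configurations that occur more often
#' than lower-order structure predicts; negative entries mark socially avoided
#' configurations. For unpenalized models the zero-sum gauge parameters are
#' used (the fitted gauge is arbitrary there); penalized models contribute
#' their exact-zero pattern directly.
#'
#' @param model A [maxent()] model.
#' @param top_k Keep only the `top_k` strongest positive and `top_k` strongest
#'   negative entries per order (default all).
#' @param threshold Drop entries with `|strength| <= threshold`.
#' @return A data frame of class `"interaction_map"` with columns `order`,
#'   `animals`, `zones`, `strength`, sorted by `|strength|` descending (ties:
#'   lexicographic animal subset, then zones); attribute `n_zero_by_order`
#'   counts zero parameters per order.
#' @export
interaction_map <- function(model, top_k = Inf, threshold = 0) {
  stopifnot(inherits(model, "maxent"))
  params <- if (model$epsilon > 0) model$params
            else coef(model, gauge = "zero.sum")
  params <- params[setdiff(names(params), "(const)")]
  ords <- lengths(lapply(names(params), key_subset))
  keep <- ords >= 2L
  n_zero <- vapply(sort(unique(ords)), function(k) {
    sum(unlist(params[ords == k], use.names = FALSE) == 0)
  }, numeric(1))
  names(n_zero) <- sort(unique(ords))
  rows <- lapply(which(keep), function(i) {
    s <- key_subset(names(params)[i])
    v <- as.vector(params[[i]])
    nz <- which(v != 0 & abs(v) > threshold)
    if (!length(nz)) return(NULL)
    zones <- arrayInd(nz, .dim = rep(model$n_zones, length(s)))
    data.frame(order = length(s),
               animals = subset_key(s),
               zones = apply(zones, 1L, paste, collapse = ","),
               strength = v[nz])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(order = integer(), animals = character(),
                                      zones = character(), strength = numeric())
  out <- out[order(-abs(out$strength), out$animals, out$zones), , drop = FALSE]
  if (is.finite(top_k) && nrow(out)) {
    sel <- unlist(lapply(split(seq_len(nrow(out)), out$order), function(ix) {
      pos <- ix[out$strength[ix] > 0]
      neg <- ix[out$strength[ix] < 0]
      c(utils::head(pos, top_k), utils::head(neg, top_k))
    }))
    out <- out[sort(sel), , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, n_zero_by_order = n_zero,
            class = c("interaction_map", "data.frame"))
}

#' Write an interaction map as delimited text
#'
#' Columns `order, animals, zones, strength`, sorted by `|strength|`
#' descending with lexicographic tie-breaks, so the output is byte-stable.
#'
#' @param map An [interaction_map()].
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_interaction_map <- function(map, path) {
  df <- as.data.frame(map)
  df$strength <- formatC(df$strength, digits = 17, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
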