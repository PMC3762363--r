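# Zero-sum gauge. The indicator parameterization is over-complete (indicator
# features sum to 1 per animal), so the fitted distribution is unique but the
# parameter blocks are not. The zero-sum gauge -- every block sums to zero
# along each of its zone axes -- is the unique representative that makes
# interaction signs and strengths well-defined and comparable across groups.
# It is computed as the ANOVA (effects) decomposition of log2 p over the full
# joint table, which exists whenever the table is strictly positive; terms of
# order above the model's order vanish identically (up to convergence error).

#' Zero-sum gauge parameters of a model or distribution
#'
#' Decomposes `log2 p` of the model's joint table into a constant plus
#' zero-sum effect blocks, one per animal subset: singleton fields, pairwise
#' couplings, triplet couplings, and so on. Each block sums to zero along
#' every zone axis, which fixes the gauge freedom of the indicator
#' parameterization.
#'
#' @param x A [maxent()] model or [joint_distribution()] with strictly
#'   positive probabilities.
#' @param max_order Highest order of blocks to return (default: all).
#' @return Named list of effect arrays keyed by animal subset (e.g. `"1,3"`),
#'   plus a `"(const)"` scalar, all in log2 units.
#' @export
zero_sum_gauge <- function(x, max_order = NULL) {
  dist <- as_joint_dist(x)
  p <- unclass(dist)
  if (any(p <= 0))
    abort_validation("zero-sum gauge requires a strictly positive joint table")
  N <- n_animals(dist)
  max_order <- as.integer(max_order %||% N)
  f <- log2(p)
  subs <- animal_subsets(N, N)
  # means of f over all axes outside each subset
  m <- lapply(subs, function(s) {
    mb <- apply(f, s, mean)
    if (length(s) == 1L) mb <- array(mb, dim = length(mb))
    mb
  })
  names(m) <- vapply(subs, subset_key, "")
  m0 <- mean(f)
  cfg_cache <- new.env(parent = emptyenv())
  effects <- list("(const)" = m0)
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    k <- length(s)
    if (k > max_order) next
    e <- m[[i]]
    # inclusion-exclusion over proper sub-subsets
    sign0 <- (-1)^k
    e <- e + sign0 * m0
    if (k > 1L) {
      Z <- n_zones(dist)
      grid_key <- as.character(k)
      grid <- cfg_cache[[grid_key]]
      if (is.null(grid)) {
        grid <- config_grid(k, Z)
        cfg_cache[[grid_key]] <- grid
      }
      for (j in seq_len(k - 1L)) {
        cb <- utils::combn(k, j)
        for (c2 in seq_len(ncol(cb))) {
          b_local <- cb[, c2]
          b_global <- s[b_local]
          mb <- as.vector(m[[subset_key(b_global)]])
          lin <- subset_linear_index(grid, b_local, Z)
          e <- e + array((-1)^(k - j) * mb[lin], dim = dim(e))
        }
      }
    }
    effects[[subset_key(s)]] <- e
  }
  effects
}
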