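# Information-theoretic readouts on occupancy series: how much of the
# uncertainty about one animal's location can be read from the others.

# Empirical joint probability table over a subset of animals (columns).
empirical_subset_table <- function(series, animals) {
  Z <- series$n_zones
  K <- check_enumerable(Z, length(animals), "empirical_subset_table")
  idx <- subset_linear_index(series$states, sort(animals), Z)
  # order animals ascending internally; callers only use symmetric functionals
  array(tabulate(idx, nbins = K) / nrow(series$states),
        dim = rep(Z, length(animals)))
}

# I(target ; joint of sources) in bits, plug-in, from a series.
series_group_information <- function(series, target, sources) {
  h_t <- entropy(empirical_subset_table(series, target))
  h_s <- entropy(empirical_subset_table(series, sources))
  h_ts <- entropy(empirical_subset_table(series, c(target, sources)))
  max(h_t + h_s - h_ts, 0)
}

#' Fraction of an animal's location uncertainty readable from others
#'
#' The normalized information \eqn{I(x_i; \{x_j\}_{j \in sources}) / H(x_i)}:
#' the fraction of the uncertainty about the target animal's zone that is
#' removed by knowing the joint zones of the source animals. Lies in [0, 1];
#' 1 means the target is a deterministic function of the sources, 0 means
#' independence.
#'
#' @param series A [config_series()].
#' @param target Animal index.
#' @param sources Nonempty set of animal indices, excluding `target`.
#' @return Fraction in [0, 1]; `NaN` with a warning if the target's entropy is
#'   zero (its location is constant).
#' @export
information_fraction <- function(series, target, sources) {
  stopifnot(inherits(series, "config_series"))
  N <- n_animals(series)
  target <- check_animal(target, N)
  sources <- as.integer(sources)
  if (!length(sources) || anyNA(sources) || any(sources < 1L | sources > N))
    abort_argument("sources must be a nonempty set of valid animal indices")
  if (target %in% sources) abort_argument("target must not be among sources")
  h_t <- entropy(empirical_subset_table(series, target))
  if (h_t == 0) {
    warning("target animal has zero location entropy; fraction undefined")
    return(NaN)
  }
  min(series_group_information(series, target, unique(sources)) / h_t, 1)
}

#' Naive additive pairwise information fraction
#'
#' The sum over all other animals j of \eqn{I(x_i; x_j) / H(x_i)}. Unlike
#' [information_fraction()] this sum is not bounded by 1; comparing the two
#' exposes synergy: when the joint fraction greatly exceeds the pairwise sum,
#' the information about the target is carried by higher-order combinations of
#' the others' locations, not by any pair.
#'
#' @param series A [config_series()].
#' @param target Animal index.
#' @return Nonnegative sum of pairwise fractions; `NaN` with a warning if the
#'   target's entropy is zero.
#' @export
naive_pairwise_fraction <- function(series, target) {
  stopifnot(inherits(series, "config_series"))
  N <- n_animals(series)
  if (N < 2L) abort_argument("need at least 2 animals")
  target <- check_animal(target, N)
  h_t <- entropy(empirical_subset_table(series, target))
  if (h_t == 0) {
    warning("target animal has zero location entropy; fraction undefined")
    return(NaN)
  }
  others <- setdiff(seq_len(N), target)
  sum(vapply(others, function(j) {
    series_group_information(series, target, j) / h_t
  }, numeric(1)))
}

#' Per-animal information report
#'
#' For each animal: its location entropy, the fraction of that uncertainty
#' readable from the joint locations of all other animals, and the naive
#' additive pairwise fraction. The gap between the last two columns is the
#' synergy signature of the group.
#'
#' @param series A [config_series()].
#' @return A data frame with columns `animal`, `entropy_bits`,
#'   `group_fraction`, `pairwise_sum`.
#' @export
info_report <- function(series) {
  stopifnot(inherits(series, "config_series"))
  N <- n_animals(series)
  rows <- lapply(seq_len(N), function(i) {
    data.frame(animal = series$animal_ids[i],
               entropy_bits = entropy(empirical_subset_table(series, i)),
               group_fraction = if (N > 1L)
                 information_fraction(series, i, setdiff(seq_len(N), i)) else NA_real_,
               pairwise_sum = if (N > 1L) naive_pairwise_fraction(series, i)
               else NA_real_)
  })
  do.call(rbind, rows)
}
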