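#' Joint configuration distribution
#'
#' A probability table over all Z^N joint configurations, stored as an N-way
#' array with `dim = rep(Z, N)`; margin i is animal i and animal 1 varies
#' fastest in the linear layout. `sample_count` records how many time bins the
#' table was estimated from (0 for an analytic/model table).
#'
#' @param probabilities Numeric array (or vector reshaped by `n_animals`) of
#'   nonnegative entries summing to 1 within 1e-10.
#' @param sample_count Integer; 0 for analytic tables.
#' @param n_animals Required if `probabilities` is not already an array with
#'   equal extents.
#' @param animal_ids,legend Optional annotations.
#' @return An object of class `"joint_dist"` (an array with attributes).
#' @export
joint_distribution <- function(probabilities, sample_count = 0L,
                               n_animals = NULL, animal_ids = NULL,
                               legend = NULL) {
  p <- probabilities
  if (is.null(dim(p))) {
    if (is.null(n_animals)) abort_argument("n_animals needed for a flat probability vector")
    Z <- round(length(p)^(1 / n_animals))
    if (Z^n_animals != length(p)) abort_argument("length is not Z^N for any integer Z")
    dim(p) <- rep(Z, n_animals)
  }
  d <- dim(p)
  if (length(unique(d)) != 1L) abort_validation("all array extents must equal the zone count")
  if (any(p < -1e-12)) abort_validation("probabilities must be nonnegative")
  p[p < 0] <- 0
  if (abs(sum(p) - 1) > 1e-10) abort_validation("probabilities must sum to 1 within 1e-10")
  structure(as.array(p), class = "joint_dist",
            sample_count = as.integer(sample_count),
            animal_ids = animal_ids, legend = legend)
}

#' @export
n_animals.joint_dist <- function(x) length(dim(x))

n_zones <- function(x) UseMethod("n_zones")
#' @export
n_zones.joint_dist <- function(x) dim(x)[1L]
#' @export
n_zones.config_series <- function(x) x$n_zones

#' Number of samples behind a distribution estimate
#'
#' Returns the `sample_count` attribute of a [joint_distribution()] (0 for
#' analytic tables), so downstream users can assess plug-in estimation bias.
#'
#' @param x A [joint_distribution()].
#' @return Integer count.
#' @export
sample_count <- function(x) attr(x, "sample_count") %||% 0L

#' @export
print.joint_dist <- function(x, ...) {
  N <- n_animals(x); Z <- n_zones(x)
  cat(sprintf("Joint configuration distribution: %d animals x %d zones (%d states)\n",
              N, Z, Z^N))
  cat(sprintf("  occupied states: %d;  entropy: %.4f bits;  sample count: %d\n",
              sum(x > 0), entropy(x), sample_count(x)))
  invisible(x)
}

as_joint_dist <- function(x) {
  if (inherits(x, "joint_dist")) return(x)
  if (inherits(x, "config_series")) return(empirical_distribution(x))
  if (inherits(x, "maxent")) return(x$table)
  abort_argument("expected a joint_dist, config_series or maxent model")
}

#' Marginal tables of a joint distribution
#'
#' Exact summations of the joint table over every animal subset of size up to
#' `order`. These tables are the constraints of the order-`order` maximum
#' entropy model; lower-order tables are marginalization-consistent with
#' higher-order ones by construction.
#'
#' @param x A [joint_distribution()], [config_series()] or fitted model.
#' @param order Maximum subset size, `1 <= order <= N`.
#' @return An object of class `"marginal_set"`: a list with `order`,
#'   `n_animals`, `n_zones`, `sample_count` and `tables` (named by subset key
#'   such as `"1,3"`, each an array over the subset's zones).
#' @export
marginal_set <- function(x, order) {
  dist <- as_joint_dist(x)
  N <- n_animals(dist)
  if (order < 1 || order > N) abort_argument(sprintf("order must be in 1..%d", N))
  subs <- animal_subsets(N, order)
  tables <- lapply(subs, function(s) {
    m <- apply(unclass(dist), s, sum)
    if (length(s) == 1L) m <- array(m, dim = length(m))
    m
  })
  names(tables) <- vapply(subs, subset_key, "")
  structure(list(order = as.integer(order), n_animals = N,
                 n_zones = n_zones(dist), sample_count = sample_count(dist),
                 tables = tables),
            class = "marginal_set")
}

#' @export
print.marginal_set <- function(x, ...) {
  cat(sprintf("Marginal set: order %d, %d animals x %d zones, %d tables\n",
              x$order, x$n_animals, x$n_zones, length(x$tables)))
  invisible(x)
}

#' Relabel animals of a joint distribution
#'
#' Permutes the configuration axes so that axis k of the result is axis
#' `perm[k]` of the input. Entropy and all symmetric functionals are
#' invariant under relabeling.
#'
#' @param dist A [joint_distribution()].
#' @param perm Integer permutation of `1:N`.
#' @return A [joint_distribution()].
#' @export
permute_animals <- function(dist, perm) {
  stopifnot(inherits(dist, "joint_dist"))
  N <- n_animals(dist)
  if (length(perm) != N || !setequal(perm, seq_len(N)))
    abort_argument(sprintf("perm must be a permutation of 1..%d", N))
  joint_distribution(aperm(unclass(dist), as.integer(perm)),
                     sample_count = sample_count(dist),
                     animal_ids = attr(dist, "animal_ids")[perm],
                     legend = attr(dist, "legend"))
}

#' Shannon entropy of a probability table (bits)
#'
#' Plug-in entropy \eqn{H = -\sum_s p_s \log_2 p_s} with the convention
#' \eqn{0 \log 0 = 0}. No finite-sample bias correction is applied.
#'
#' @param p Numeric vector or array of probabilities (nonnegative, summing to
#'   1 within 1e-8), or a [joint_distribution()].
#' @return Entropy in bits.
#' @examples
#' entropy(rep(0.1, 10))  # log2(10)
#' @export
entropy <- function(p) {
  p <- as.vector(unclass(p))
  if (any(p < -1e-12)) abort_validation("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-8) abort_validation("probabilities must sum to 1")
  -sum(xlog2x(p[p > 0]))
}

#' Mutual information of a two-way probability table (bits)
#'
#' \eqn{I(X;Y) = H(X) + H(Y) - H(X,Y)} from the plug-in entropies of the joint
#' table and its marginals. Tiny negative values from rounding are clamped to
#' zero.
#'
#' @param joint Numeric matrix: joint probability table over (x, y).
#' @return Mutual information in bits (>= 0).
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  mi <- entropy(rowSums(joint)) + entropy(colSums(joint)) - entropy(joint)
  max(mi, 0)
}

#' Multi-information (total correlation) of a joint distribution (bits)
#'
#' \eqn{I_N = \sum_j H(x_j) - H(x_1,\dots,x_N)}: the Kullback-Leibler
#' divergence of the joint distribution from the product of its single-animal
#' marginals, i.e. the total amount of statistical structure in the group
#' beyond individual zone preferences. For N = 2 it equals the mutual
#' information.
#'
#' @param dist A [joint_distribution()] (or series / model coercible to one).
#' @return Multi-information in bits (>= 0 up to rounding).
#' @export
multi_information <- function(dist) {
  dist <- as_joint_dist(dist)
  N <- n_animals(dist)
  hs <- vapply(seq_len(N), function(i) entropy(apply(unclass(dist), i, sum)),
               numeric(1))
  max(sum(hs) - entropy(dist), 0)
}

#' Jensen-Shannon divergence between two joint distributions (bits)
#'
#' \eqn{D_{JS}(p,q) = \tfrac12 KL(p\|m) + \tfrac12 KL(q\|m)} with
#' \eqn{m = (p+q)/2}, base-2 logarithms; bounded in [0, 1], equal to 0 iff
#' p = q and to 1 when the supports are disjoint.
#'
#' @param p,q [joint_distribution()] objects (or coercible) on the same state
#'   space.
#' @return Divergence in [0, 1].
#' @export
js_divergence <- function(p, q) {
  p <- as.vector(unclass(as_joint_dist(p)))
  q <- as.vector(unclass(as_joint_dist(q)))
  if (length(p) != length(q)) abort_argument("distributions live on different state spaces")
  m <- (p + q) / 2
  kl <- function(a) {
    pos <- a > 0
    sum(a[pos] * (log2(a[pos]) - log2(m[pos])))
  }
  min(max((kl(p) + kl(q)) / 2, 0), 1)
}

#' Serialize a joint distribution as sparse text
#'
#' One line per occupied configuration: the zone codes of animals 1..N, then
#' the probability, comma-separated. Lines are ordered lexicographically with
#' animal 1 slowest, so output is byte-stable. A header records N, Z and the
#' sample count.
#'
#' @param dist A [joint_distribution()].
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "joint_dist"))
  N <- n_animals(dist); Z <- n_zones(dist)
  cfg <- config_grid(N, Z)
  p <- as.vector(unclass(dist))
  keep <- which(p > 0)
  # lexicographic with animal 1 slowest
  ord <- keep[do.call(order, as.data.frame(cfg[keep, N:1, drop = FALSE]))]
  header <- sprintf("# joint_dist n_animals=%d n_zones=%d sample_count=%d",
                    N, Z, sample_count(dist))
  rows <- paste(apply(cfg[ord, , drop = FALSE], 1L, paste, collapse = ","),
                formatC(p[ord], digits = 17, format = "g"), sep = ",")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a joint distribution written by [write_distribution()]
#'
#' @param path File path.
#' @return A [joint_distribution()].
#' @export
read_distribution <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path)
  h <- regmatches(lines[1L], gregexpr("[0-9]+", lines[1L]))[[1L]]
  if (!startsWith(lines[1L], "# joint_dist") || length(h) < 3L)
    abort_parse("not a joint_dist file")
  N <- as.integer(h[1L]); Z <- as.integer(h[2L]); sc <- as.integer(h[3L])
  p <- numeric(Z^N)
  if (length(lines) > 1L) {
    parts <- strsplit(lines[-1L], ",", fixed = TRUE)
    m <- matrix(as.numeric(unlist(parts)), ncol = N + 1L, byrow = TRUE)
    states <- m[, seq_len(N), drop = FALSE]
    storage.mode(states) <- "integer"
    p[config_linear_index(states, Z)] <- m[, N + 1L]
  }
  p <- p / sum(p)
  joint_distribution(array(p, dim = rep(Z, N)), sample_count = sc)
}
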