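# Internal helpers: error conditions, state-space enumeration, subset indexing.

# Largest joint state space we will enumerate exactly. Beyond this the exact
# fitting/sampling machinery does not apply and callers are directed to the
# Markov-chain sampler or refused.
MAX_ENUMERABLE_STATES <- 1e7

abort <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "groupmaxent_error")))
}
abort_validation  <- function(msg) abort(msg, "groupmaxent_validation_error")
abort_argument    <- function(msg) abort(msg, c("groupmaxent_argument_error",
                                                "groupmaxent_validation_error"))
abort_parse       <- function(msg) abort(msg, c("groupmaxent_parse_error",
                                                "groupmaxent_validation_error"))
abort_convergence <- function(msg) abort(msg, "groupmaxent_convergence_error")
abort_io          <- function(msg) abort(msg, "groupmaxent_io_error")
abort_capability  <- function(msg) abort(msg, c("groupmaxent_capability_error",
                                                "groupmaxent_validation_error"))

check_enumerable <- function(n_zones, n_animals, what = "operation") {
  n_states <- n_zones^n_animals
  if (n_states > MAX_ENUMERABLE_STATES) {
    abort_capability(sprintf(
      "%s requires enumerating %d^%d joint states, above the exact-enumeration guard (%g); use sample_markov_series() or reduce the state space",
      what, n_zones, n_animals, MAX_ENUMERABLE_STATES))
  }
  as.integer(n_states)
}

# All animal subsets of sizes 1..order, each an ascending integer vector,
# ordered by size then lexicographically.
animal_subsets <- function(n_animals, order) {
  out <- list()
  for (k in seq_len(order)) {
    cm <- utils::combn(n_animals, k)
    for (j in seq_len(ncol(cm))) out[[length(out) + 1L]] <- as.integer(cm[, j])
  }
  out
}

subset_key <- function(s) paste(s, collapse = ",")
key_subset <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])

# Enumerate all Z^N configurations as an integer matrix, one row per joint
# state, column i = animal i. Row order is the linear layout of an array with
# dim = rep(Z, N): animal 1 varies fastest.
config_grid <- function(n_animals, n_zones) {
  m <- as.matrix(expand.grid(rep(list(seq_len(n_zones)), n_animals),
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# Linear index of each configuration row into the marginal table of `subset`
# (an array with dim rep(Z, length(subset)), first subset member fastest).
subset_linear_index <- function(states, subset, n_zones) {
  idx <- states[, subset[1L]] - 1L
  if (length(subset) > 1L) {
    stride <- 1L
    for (j in 2:length(subset)) {
      stride <- stride * n_zones
      idx <- idx + (states[, subset[j]] - 1L) * stride
    }
  }
  idx + 1L
}

# Linear index of full configurations (all animals) into the joint table.
config_linear_index <- function(states, n_zones) {
  subset_linear_index(states, seq_len(ncol(states)), n_zones)
}

# log2-sum-exp2 with overflow guard.
log2_sum_exp2 <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log2(sum(2^(x - m)))
}

# x * log2(x) with the 0 log 0 = 0 convention.
xlog2x <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

# All permutations of 1..n in lexicographic order.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", factorial(n))
  i <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (p in sub) {
      i <- i + 1L
      out[[i]] <- c(first, rest[p])
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
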