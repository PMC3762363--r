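#' Permutation-minimized distance between two groups
#'
#' Animal labels within a group are arbitrary, so two groups are compared by
#' the smallest Jensen-Shannon divergence over all relabelings of one group's
#' animals:
#' \deqn{d(i,j) = \min_\pi D_{JS}\big(p_i(\{x_k\}),\, p_j(\pi\{x_k\})\big).}
#' The search over all N! permutations is exhaustive (guarded at N <= 8), so
#' the minimum is exact; ties are broken by the lexicographically smallest
#' permutation.
#'
#' @param p,q [joint_distribution()]s or fitted [maxent()] models on the same
#'   state space.
#' @return A list of class `"permutation_result"`: `distance`, `permutation`,
#'   and `identity_distance` (the unpermuted divergence, always >= distance).
#' @export
min_permutation_distance <- function(p, q) {
  p <- as_joint_dist(p); q <- as_joint_dist(q)
  N <- n_animals(p)
  if (N != n_animals(q) || n_zones(p) != n_zones(q))
    abort_argument("distributions live on different state spaces")
  if (N > 8L) abort_capability("exhaustive permutation search is limited to N <= 8")
  perms <- all_permutations(N)
  best <- Inf; best_perm <- perms[[1L]]
  identity_d <- NA_real_
  qarr <- unclass(q)
  parr <- as.vector(unclass(p))
  for (perm in perms) {
    qp <- as.vector(aperm(qarr, perm))
    m <- (parr + qp) / 2
    pos_p <- parr > 0; pos_q <- qp > 0
    d <- (sum(parr[pos_p] * (log2(parr[pos_p]) - log2(m[pos_p]))) +
          sum(qp[pos_q] * (log2(qp[pos_q]) - log2(m[pos_q])))) / 2
    d <- min(max(d, 0), 1)
    if (all(perm == seq_len(N))) identity_d <- d
    if (d < best - 1e-15) { best <- d; best_perm <- perm }
  }
  structure(list(distance = best, permutation = best_perm,
                 identity_distance = identity_d),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation-minimized JS distance: %.5f (identity: %.5f) at pi = (%s)\n",
              x$distance, x$identity_distance,
              paste(x$permutation, collapse = " ")))
  invisible(x)
}

#' Pairwise similarity matrix of fitted group models
#'
#' Computes [min_permutation_distance()] between every pair of groups
#' (typically their regularized third-order models). With cohort labels, also
#' reports the mean within-cohort and between-cohort distances.
#'
#' @param groups List of [maxent()] models or [joint_distribution()]s on a
#'   common state space.
#' @param labels Optional group names.
#' @param cohort Optional cohort label per group.
#' @return An object of class `"similarity_matrix"`: list with `distance`
#'   (symmetric matrix, zero diagonal), `cohort`, `within_mean`,
#'   `between_mean`.
#' @export
similarity_matrix <- function(groups, labels = NULL, cohort = NULL) {
  n <- length(groups)
  if (n < 2L) abort_argument("need at least 2 groups")
  dists <- lapply(groups, as_joint_dist)
  labels <- labels %||% (names(groups) %||% paste0("g", seq_len(n)))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- min_permutation_distance(dists[[i]], dists[[j]])$distance
    }
  }
  within_mean <- between_mean <- NA_real_
  if (!is.null(cohort)) {
    if (length(cohort) != n) abort_argument("cohort must have one label per group")
    same <- outer(cohort, cohort, "==") & upper.tri(d)
    diff <- outer(cohort, cohort, "!=") & upper.tri(d)
    if (any(same)) within_mean <- mean(d[same])
    if (any(diff)) between_mean <- mean(d[diff])
  }
  structure(list(distance = d, cohort = cohort,
                 within_mean = within_mean, between_mean = between_mean),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("Group similarity matrix (%d groups, permutation-minimized JS):\n",
              nrow(x$distance)))
  print(round(x$distance, 4))
  if (!is.na(x$within_mean))
    cat(sprintf("  mean distance within cohorts: %.4f;  between cohorts: %.4f\n",
                x$within_mean, x$between_mean))
  invisible(x)
}

#' Write a similarity matrix as labeled delimited text
#' @param x A [similarity_matrix()].
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_similarity_matrix <- function(x, path) {
  m <- x$distance
  df <- data.frame(group = rownames(m),
                   cohort = if (is.null(x$cohort)) "" else x$cohort,
                   formatC(m, digits = 17, format = "g"),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cohort-level correlation summaries
#'
#' Runs [decompose()] on each (group, day) series and aggregates the
#' multi-information and per-order contribution fractions across groups:
#' mean and standard error per cohort and day. With a single group per
#' cohort-day cell the standard error is `NA`.
#'
#' @param series_list List of [config_series()], one per group-day.
#' @param cohort Cohort label per series.
#' @param day Day index per series (defaults to 1).
#' @param group Group id per series (defaults to `g1, g2, ...`).
#' @param max_order,epsilon,control Passed to [decompose()].
#' @return An object of class `"cohort_summary"`: list with `per_group` (one
#'   row per group-day and statistic, long format) and `summary` (mean and
#'   sem per cohort-day-statistic).
#' @export
cohort_summary <- function(series_list, cohort, day = NULL, group = NULL,
                           max_order = NULL, epsilon = 0,
                           control = maxent_control()) {
  n <- length(series_list)
  if (length(cohort) != n) abort_argument("cohort must have one label per series")
  day <- day %||% rep(1L, n)
  group <- group %||% paste0("g", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    dec <- decompose(series_list[[i]], max_order = max_order,
                     epsilon = epsilon, control = control)
    stats <- c(I_N = unname(dec$multi_information),
               stats::setNames(dec$contributions,
                               paste0(names(dec$contributions), "_bits")),
               stats::setNames(dec$fractions,
                               paste0(names(dec$contributions), "_frac")))
    data.frame(group = group[i], cohort = cohort[i], day = day[i],
               statistic = names(stats), value = unname(stats))
  })
  per_group <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ cohort + day + statistic, per_group,
                          function(v) c(mean = mean(v),
                                        sem = stats::sd(v) / sqrt(length(v)),
                                        n = length(v)))
  summary_df <- cbind(agg[c("cohort", "day", "statistic")],
                      as.data.frame(agg$value))
  structure(list(per_group = per_group, summary = summary_df),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (mean +/- sem across groups):\n")
  s <- x$summary
  s$mean <- round(s$mean, 4); s$sem <- round(s$sem, 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write a cohort summary as tidy long-format text
#' @param x A [cohort_summary()].
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_cohort_summary <- function(x, path) {
  df <- x$per_group
  df$value <- formatC(df$value, digits = 17, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
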