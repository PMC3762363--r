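# Independent oracle: direct constrained entropy maximization over the full
# probability simplex, by augmented-Lagrangian BFGS on a softmax
# parameterization. Shares no code with the package's scaling/gradient
# fitter; used to certify small maxent fits.

# Constraint matrix: one row per (subset, zone-cell) feature, A %*% q = the
# stacked marginal vector.
marginal_constraint_matrix <- function(n_animals, n_zones, order) {
  cfg <- groupmaxent:::config_grid(n_animals, n_zones)
  subs <- groupmaxent:::animal_subsets(n_animals, order)
  K <- nrow(cfg)
  rows <- list()
  for (s in subs) {
    lin <- groupmaxent:::subset_linear_index(cfg, s, n_zones)
    ncell <- n_zones^length(s)
    block <- matrix(0, ncell, K)
    block[cbind(lin, seq_len(K))] <- 1
    rows[[length(rows) + 1L]] <- block
  }
  do.call(rbind, rows)
}

# Maximize H(q) (bits) subject to A q = b over the simplex; q = softmax(u).
oracle_maxent_simplex <- function(dist, order, outer_iter = 40) {
  p_emp <- as.vector(unclass(dist))
  N <- length(dim(dist)); Z <- dim(dist)[1]
  A <- marginal_constraint_matrix(N, Z, order)
  b <- as.vector(A %*% p_emp)
  K <- length(p_emp)
  u <- rep(0, K)
  lam <- rep(0, nrow(A))
  mu <- 10
  ln2 <- log(2)
  for (it in seq_len(outer_iter)) {
    obj <- function(u) {
      w <- exp(u - max(u)); q <- w / sum(w)
      r <- as.vector(A %*% q) - b
      sum(groupmaxent:::xlog2x(q)) + sum(lam * r) + (mu / 2) * sum(r * r)
    }
    grad <- function(u) {
      w <- exp(u - max(u)); q <- w / sum(w)
      r <- as.vector(A %*% q) - b
      gq <- (log2(pmax(q, 1e-300)) + 1 / ln2) + as.vector(crossprod(A, lam + mu * r))
      q * (gq - sum(q * gq))
    }
    res <- stats::optim(u, obj, grad, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-15))
    u <- res$par
    w <- exp(u - max(u)); q <- w / sum(w)
    r <- as.vector(A %*% q) - b
    if (max(abs(r)) < 1e-11 && it > 3) break
    lam <- lam + mu * r
    mu <- min(mu * 4, 1e9)
  }
  array(q, dim = rep(Z, N))
}
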