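#' Control parameters for maximum entropy fitting
#'
#' @param tol Convergence tolerance: for unpenalized fits, the maximum
#'   absolute deviation between model marginals and their constraints; for
#'   L1-penalized fits, the sup-norm of the proximal-gradient residual (both
#'   in probability / bits-per-sample units).
#' @param ipf_iter Maximum generalized-iterative-scaling sweeps used as the
#'   warm start.
#' @param grad_iter Maximum exact-gradient ascent iterations (with
#'   backtracking line search) after the scaling warm-up.
#' @param prox_iter Maximum proximal-gradient iterations for penalized fits.
#' @param on_nonconvergence `"error"` or `"warn"`.
#' @return A list of class `"maxent_control"`.
#' @export
maxent_control <- function(tol = 1e-6, ipf_iter = 1000L, grad_iter = 500L,
                           prox_iter = 20000L, on_nonconvergence = "error") {
  if (!(tol > 0)) abort_argument("tol must be > 0")
  structure(list(tol = tol, ipf_iter = as.integer(ipf_iter),
                 grad_iter = as.integer(grad_iter),
                 prox_iter = as.integer(prox_iter),
                 on_nonconvergence = match.arg(on_nonconvergence,
                                               c("error", "warn"))),
            class = "maxent_control")
}

# Guard against zero constraint cells, which would drive parameters to -Inf.
# Every table is mixed with the uniform distribution using one common weight
# w, which (i) bounds each order-k marginal cell below by w / Z^k >= the
# target floor of 1/(10 T), kept at or below sampling noise, and (ii) keeps
# the whole constraint set self-consistent, because mixed tables are exact
# marginals of the single mixed joint (1-w) p + w u. Per-table flooring would
# break that consistency and leave the scaling algorithm without an exact
# fixed point. No smoothing is applied when all cells already clear the
# floor.
smoothed_targets <- function(marg, order) {
  floor_val <- if (marg$sample_count > 0) 1 / (10 * marg$sample_count) else 1e-12
  Z <- marg$n_zones
  keep <- lengths(lapply(names(marg$tables), key_subset)) <= order
  tables <- marg$tables[keep]
  min_cell <- min(vapply(tables, min, numeric(1)))
  w <- 0
  if (min_cell < floor_val) {
    w <- min(floor_val * Z^order, 0.5)
    tables <- lapply(tables, function(tab) {
      (1 - w) * tab + w / length(tab)
    })
  }
  list(tables = tables, smoothing_weight = w,
       n_floored = if (w > 0) sum(vapply(marg$tables[keep], function(tab)
         sum(tab < floor_val), numeric(1))) else 0L)
}

zero_params <- function(subsets, n_zones) {
  out <- lapply(subsets, function(s) array(0, dim = rep(n_zones, length(s))))
  names(out) <- vapply(subsets, subset_key, "")
  out
}

# log2 of the unnormalized model table from parameter blocks.
params_log_table <- function(params, idx, n_states) {
  logp <- numeric(n_states)
  for (k in names(params)) logp <- logp + as.vector(params[[k]])[idx[[k]]]
  logp
}

model_marginals <- function(ptab, subsets) {
  lapply(subsets, function(s) {
    m <- apply(ptab, s, sum)
    if (length(s) == 1L) m <- array(m, dim = length(m))
    m
  })
}

max_marginal_residual <- function(margs, targets) {
  max(vapply(seq_along(margs), function(i) max(abs(margs[[i]] - targets[[i]])),
             numeric(1)))
}

# Generalized iterative scaling: multiplicative per-subset updates
# p <- p * target_S / p_S, accumulating log2 factors into the parameter
# blocks so that the converged table is exactly exp2(sum of features).
fit_ipf <- function(targets, subsets, n_animals, n_zones, idx, tol, max_sweeps) {
  K <- n_zones^n_animals
  p <- array(1 / K, dim = rep(n_zones, n_animals))
  lambda <- zero_params(subsets, n_zones)
  keys <- names(lambda)
  sweeps <- 0L
  resid <- Inf
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    for (i in seq_along(subsets)) {
      m <- apply(p, subsets[[i]], sum)
      r <- as.vector(targets[[i]]) / as.vector(m)
      p <- p * r[idx[[keys[i]]]]
      p <- p / sum(p)
      lambda[[i]] <- lambda[[i]] + array(log2(r), dim = dim(lambda[[i]]) %||% length(r))
    }
    resid <- max_marginal_residual(model_marginals(p, subsets), targets)
    if (resid <= tol) break
  }
  list(p = p, lambda = lambda, sweeps = sweeps, resid = resid)
}

# Exact-gradient ascent on the dual (average log2-likelihood as a function of
# the natural parameters), with backtracking line search. Gradient per
# feature = constraint minus model marginal.
fit_gradient <- function(lambda, targets, subsets, n_zones, idx, tol, max_iter) {
  keys <- names(lambda)
  blk_len <- vapply(lambda, length, integer(1))
  t_flat <- unlist(lapply(targets, as.vector), use.names = FALSE)
  lam <- unlist(lambda, use.names = FALSE)
  relist_params <- function(v) {
    out <- vector("list", length(lambda))
    names(out) <- keys
    off <- 0L
    for (i in seq_along(lambda)) {
      out[[i]] <- array(v[off + seq_len(blk_len[i])], dim = dim(lambda[[i]]))
      off <- off + blk_len[i]
    }
    out
  }
  K <- length(idx[[keys[1L]]])
  n_anim <- round(log(K) / log(n_zones))
  eval_at <- function(v) {
    pl <- relist_params(v)
    logp <- params_log_table(pl, idx, K)
    logZ <- log2_sum_exp2(logp)
    ptab <- 2^(logp - logZ)
    dim(ptab) <- rep(n_zones, n_anim)
    margs <- model_marginals(ptab, subsets)
    list(obj = sum(v * t_flat) - logZ, p = ptab,
         grad = t_flat - unlist(lapply(margs, as.vector), use.names = FALSE),
         margs = margs)
  }
  cur <- eval_at(lam)
  step <- 1
  iter <- 0L
  resid <- max_marginal_residual(cur$margs, targets)
  while (resid > tol && iter < max_iter) {
    iter <- iter + 1L
    g <- cur$grad
    gg <- sum(g * g)
    repeat {
      cand <- lam + step * g
      nxt <- eval_at(cand)
      if (nxt$obj >= cur$obj + 0.25 * step * gg || step < 1e-12) break
      step <- step / 2
    }
    lam <- cand
    cur <- nxt
    step <- min(step * 2, 1e3)
    resid <- max_marginal_residual(cur$margs, targets)
  }
  list(p = cur$p, lambda = relist_params(lam), iter = iter, resid = resid)
}

# Proximal gradient (soft-threshold / lasso) maximization of
#   sum(lambda * constraint) - log2 Z(lambda) - epsilon * sum(|lambda|).
# Backtracking on the quadratic majorization guarantees monotone ascent of the
# penalized objective; the soft-threshold step yields exact zeros.
fit_proximal <- function(targets, subsets, n_animals, n_zones, idx, epsilon,
                         tol, max_iter) {
  keys <- vapply(subsets, subset_key, "")
  K <- n_zones^n_animals
  lambda0 <- zero_params(subsets, n_zones)
  blk_len <- vapply(lambda0, length, integer(1))
  t_flat <- unlist(lapply(targets, as.vector), use.names = FALSE)
  relist_params <- function(v) {
    out <- vector("list", length(lambda0))
    names(out) <- keys
    off <- 0L
    for (i in seq_along(lambda0)) {
      out[[i]] <- array(v[off + seq_len(blk_len[i])], dim = dim(lambda0[[i]]))
      off <- off + blk_len[i]
    }
    out
  }
  smooth_at <- function(v) {
    pl <- relist_params(v)
    logp <- params_log_table(pl, idx, K)
    logZ <- log2_sum_exp2(logp)
    ptab <- 2^(logp - logZ)
    dim(ptab) <- rep(n_zones, n_animals)
    margs <- model_marginals(ptab, subsets)
    list(f = sum(v * t_flat) - logZ, p = ptab,
         grad = t_flat - unlist(lapply(margs, as.vector), use.names = FALSE),
         margs = margs)
  }
  soft <- function(v, thr) sign(v) * pmax(abs(v) - thr, 0)
  penalized <- function(st, v) st$f - epsilon * sum(abs(v))
  # KKT residual of the penalized problem at lam with smooth gradient g
  kkt_resid <- function(lam, g) {
    nz <- lam != 0
    r <- pmax(abs(g) - epsilon, 0)
    r[nz] <- abs(g[nz] - epsilon * sign(lam[nz]))
    max(r)
  }
  # FISTA with backtracking, adaptive restart and a monotone (ISTA fallback)
  # safeguard, so the penalized objective is non-decreasing by construction.
  lam <- numeric(sum(blk_len))
  cur <- smooth_at(lam)
  y <- lam
  cur_y <- cur
  tk <- 1
  L <- 1
  obj <- penalized(cur, lam)
  obj_path <- numeric(0)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    repeat {
      cand <- soft(y + cur_y$grad / L, epsilon / L)
      d <- cand - y
      nxt <- smooth_at(cand)
      if (nxt$f >= cur_y$f + sum(cur_y$grad * d) - (L / 2) * sum(d * d) ||
          L > 1e12) break
      L <- L * 2
    }
    if (penalized(nxt, cand) < obj) {
      # momentum overshoot: restart from the current iterate (plain step)
      repeat {
        cand <- soft(lam + cur$grad / L, epsilon / L)
        d <- cand - lam
        nxt <- smooth_at(cand)
        if (nxt$f >= cur$f + sum(cur$grad * d) - (L / 2) * sum(d * d) ||
            L > 1e12) break
        L <- L * 2
      }
      tk <- 1
    }
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- cand + ((tk - 1) / tk_new) * (cand - lam)
    tk <- tk_new
    lam <- cand
    cur <- nxt
    cur_y <- smooth_at(y)
    obj <- penalized(cur, lam)
    obj_path[iter] <- obj
    L <- max(L / 2, 1e-3)
    if (kkt_resid(lam, cur$grad) <= tol) { converged <- TRUE; break }
  }
  list(p = cur$p, lambda = relist_params(lam), iter = iter,
       resid = max_marginal_residual(cur$margs, targets),
       prox_resid = kkt_resid(lam, cur$grad),
       objective = obj, objective_path = obj_path, converged = converged)
}

#' Fit a maximum entropy model of group configurations
#'
#' Fits the most-random (maximum entropy) joint distribution over all animals'
#' zones that reproduces the empirical marginal tables of every animal subset
#' up to `order`. The fitted distribution has the Potts / log-linear form
#' \deqn{p(x_1,\dots,x_N) = \frac{1}{Z} \exp_2\left(\sum_i \alpha_i(x_i) +
#'   \sum_{i<j} \beta_{ij}(x_i,x_j) + \dots\right)}
#' with one indicator feature per animal subset and zone combination.
#' `order = 1` gives the independent model (the product of single-animal zone
#' preferences); `order = N` reproduces the input distribution itself.
#'
#' With `epsilon > 0` the marginal constraints become soft: the fit maximizes
#' the penalized objective (average log2-likelihood minus
#' \eqn{\epsilon \sum |\lambda|}, an L1 / lasso penalty over all parameter
#' blocks including the singleton fields), solved by proximal-gradient
#' soft-thresholding, which drives weak interaction parameters to exact zero.
#'
#' Unpenalized fits use generalized iterative scaling as a warm start followed
#' by exact-gradient ascent with backtracking line search. If any constraint
#' cell falls below `1/(10 * sample_count)`, all constraint tables are mixed
#' with the uniform distribution using one common weight so that every cell
#' clears that floor (keeping parameters finite) while the tables stay
#' mutually consistent; the perturbation is at or below sampling noise.
#'
#' @param x A [config_series()], [joint_distribution()] or [marginal_set()].
#' @param order Interaction order `1..N` of the model.
#' @param epsilon Nonnegative L1 penalty weight; 0 for hard marginal
#'   constraints. The value used for sparse interaction maps in the source
#'   analyses of this kind is `2^-16`.
#' @param control A [maxent_control()].
#' @return An object of class `"maxent"`: a list with the parameter blocks
#'   (`params`, log2 units, named by animal subset), the fitted joint table
#'   (`table`), `log_partition` (log2), convergence diagnostics and metadata.
#'   Methods: [print.maxent()], [summary.maxent()], [coef.maxent()],
#'   [predict.maxent()], [simulate.maxent()], [residuals.maxent()],
#'   [plot.maxent()].
#' @examples
#' s <- config_series(cbind(sample(1:3, 500, TRUE), sample(1:3, 500, TRUE)),
#'                    n_zones = 3)
#' m <- maxent(s, order = 1)
#' m
#' @export
maxent <- function(x, order = 2L, epsilon = 0, control = maxent_control()) {
  cl <- match.call()
  if (inherits(x, "marginal_set")) {
    marg <- x
    if (marg$order < order)
      abort_argument("marginal set order is lower than the requested model order")
    full_dist <- NULL
  } else {
    full_dist <- as_joint_dist(x)
    N <- n_animals(full_dist)
    if (order < 1 || order > N)
      abort_argument(sprintf("order must be in 1..%d", N))
    if (order == N && epsilon == 0) {
      return(maxent_endpoint(full_dist, cl))
    }
    marg <- marginal_set(full_dist, order)
  }
  N <- marg$n_animals; Z <- marg$n_zones
  if (epsilon < 0) abort_argument("epsilon must be nonnegative")
  check_enumerable(Z, N, "maxent fitting")
  subs <- lapply(names(marg$tables), key_subset)
  subs <- subs[lengths(subs) <= order]
  fl <- smoothed_targets(marg, order)
  targets <- fl$tables
  cfg <- config_grid(N, Z)
  idx <- lapply(subs, subset_linear_index, states = cfg, n_zones = Z)
  names(idx) <- vapply(subs, subset_key, "")

  if (epsilon == 0) {
    fit <- fit_ipf(targets, subs, N, Z, idx, control$tol, control$ipf_iter)
    grad_iter <- 0L
    if (fit$resid > control$tol) {
      g <- fit_gradient(fit$lambda, targets, subs, Z, idx, control$tol,
                        control$grad_iter)
      fit$p <- g$p; fit$lambda <- g$lambda; fit$resid <- g$resid
      grad_iter <- g$iter
    }
    converged <- fit$resid <= control$tol
    if (!converged) {
      msg <- sprintf("maxent fit did not converge: worst marginal residual %.3g > tol %.3g",
                     fit$resid, control$tol)
      if (control$on_nonconvergence == "error") abort_convergence(msg) else warning(msg)
    }
    iterations <- c(ipf = fit$sweeps, gradient = grad_iter)
    objective <- NA_real_
    objective_path <- NULL
  } else {
    fit <- fit_proximal(targets, subs, N, Z, idx, epsilon, control$tol,
                        control$prox_iter)
    converged <- fit$converged
    if (!converged) {
      msg <- sprintf("penalized maxent fit did not converge: proximal residual above tol %.3g (marginal residual %.3g)",
                     control$tol, fit$resid)
      if (control$on_nonconvergence == "error") abort_convergence(msg) else warning(msg)
    }
    iterations <- c(proximal = fit$iter)
    objective <- fit$objective
    objective_path <- fit$objective_path
  }
  logp <- params_log_table(fit$lambda, idx, Z^N)
  log_partition <- log2_sum_exp2(logp)
  table <- joint_distribution(array(2^(logp - log_partition), dim = rep(Z, N)),
                              sample_count = 0L,
                              animal_ids = if (!is.null(full_dist)) attr(full_dist, "animal_ids") else NULL,
                              legend = if (!is.null(full_dist)) attr(full_dist, "legend") else NULL)
  structure(list(order = as.integer(order), n_animals = N, n_zones = Z,
                 params = fit$lambda, log_partition = log_partition,
                 table = table, epsilon = epsilon,
                 constraints = targets, n_floored = fl$n_floored,
                 sample_count = marg$sample_count,
                 converged = converged, iterations = iterations,
                 residual = fit$resid, objective = objective,
                 objective_path = objective_path, call = cl),
            class = "maxent")
}

# Order-N endpoint: the maxent model constrained by the full-order marginal is
# the distribution itself; represented with a single full-order block so that
# the entropy chain terminates at the empirical entropy exactly.
maxent_endpoint <- function(dist, call) {
  N <- n_animals(dist); Z <- n_zones(dist)
  p <- as.vector(unclass(dist))
  lam <- array(log2(p * length(p)), dim = rep(Z, N))  # -Inf on empty states
  params <- stats::setNames(list(lam), subset_key(seq_len(N)))
  structure(list(order = N, n_animals = N, n_zones = Z,
                 params = params, log_partition = log2(length(p)),
                 table = dist, epsilon = 0,
                 constraints = NULL, n_floored = 0L,
                 sample_count = sample_count(dist),
                 converged = TRUE, iterations = c(ipf = 0L, gradient = 0L),
                 residual = 0, objective = NA_real_, objective_path = NULL,
                 call = call),
            class = "maxent")
}

# Construct a model directly from parameter blocks (ground-truth generators,
# model file I/O). Blocks are named by subset key; missing blocks are absent.
new_maxent <- function(params, n_animals, n_zones, epsilon = 0,
                       sample_count = 0L, call = NULL) {
  K <- check_enumerable(n_zones, n_animals, "model construction")
  order <- max(c(1L, lengths(lapply(names(params), key_subset))))
  cfg <- config_grid(n_animals, n_zones)
  idx <- lapply(names(params), function(k)
    subset_linear_index(cfg, key_subset(k), n_zones))
  names(idx) <- names(params)
  logp <- params_log_table(params, idx, K)
  logZ <- log2_sum_exp2(logp)
  table <- joint_distribution(array(2^(logp - logZ), dim = rep(n_zones, n_animals)))
  structure(list(order = as.integer(order), n_animals = as.integer(n_animals),
                 n_zones = as.integer(n_zones),
                 params = params, log_partition = logZ, table = table,
                 epsilon = epsilon, constraints = NULL, n_floored = 0L,
                 sample_count = as.integer(sample_count),
                 converged = TRUE, iterations = c(constructed = 0L),
                 residual = 0, objective = NA_real_, objective_path = NULL,
                 call = call),
            class = "maxent")
}

#' Joint distribution of a fitted model
#'
#' The exact probability table of a maximum entropy model: feature sums are
#' exponentiated (base 2) and normalized; the log-partition value is stored on
#' the model.
#'
#' @param model A [maxent()] model.
#' @return A [joint_distribution()].
#' @export
model_distribution <- function(model) {
  stopifnot(inherits(model, "maxent"))
  model$table
}
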