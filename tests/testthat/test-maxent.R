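test_that("order-1 fit is exactly the product of single-animal marginals", {
  set.seed(1)
  d <- random_dense_dist(3, 4)
  f <- maxent(d, order = 1)
  prod_p <- Reduce(outer, lapply(1:3, function(i) apply(unclass(d), i, sum)))
  expect_equal(unclass(f$table), prod_p, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("order-N fit returns the input distribution itself", {
  set.seed(2)
  s <- random_series(300, 3, 3)
  d <- empirical_distribution(s)
  f <- maxent(d, order = 3)
  expect_equal(unclass(f$table), unclass(d), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(entropy(f$table), entropy(d), tolerance = 1e-12)
})

test_that("pairwise fit of parity marginals is uniform (3 bits)", {
  f <- maxent(parity_distribution(), order = 2)
  expect_equal(entropy(f$table), 3, tolerance = 1e-9)
  expect_equal(as.vector(unclass(f$table)), rep(1 / 8, 8), tolerance = 1e-9)
  # pair marginals of the parity distribution are uniform
  ms <- marginal_set(parity_distribution(), 2)
  for (key in c("1,2", "1,3", "2,3"))
    expect_equal(as.vector(ms$tables[[key]]), rep(1 / 4, 4), tolerance = 1e-14)
})

test_that("fitted marginals match constraints within tolerance", {
  set.seed(3)
  for (rep in 1:4) {
    d <- random_dense_dist(3, 3)
    f <- maxent(d, order = 2)
    expect_true(f$converged)
    expect_lte(f$residual, 1e-6)
    res <- residuals(f)
    expect_lte(max(abs(unlist(res))), 1e-6)
  }
})

test_that("maxent fit agrees with direct simplex entropy maximization", {
  # independent oracle: augmented-Lagrangian BFGS over the full simplex
  set.seed(4)
  cases <- expand.grid(N = 2:3, Z = 2:3)
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]; Z <- cases$Z[i]
    d <- random_dense_dist(N, Z)
    for (ord in seq_len(N - 1)) {
      f <- maxent(d, order = ord, control = maxent_control(tol = 1e-9))
      q <- oracle_maxent_simplex(d, ord)
      tv <- 0.5 * sum(abs(as.vector(unclass(f$table)) - as.vector(q)))
      expect_lt(tv, 1e-6)
    }
  }
})

test_that("entropy is maximal: constraint-preserving perturbations reduce it", {
  set.seed(5)
  d <- random_dense_dist(3, 3)
  f <- maxent(d, order = 2, control = maxent_control(tol = 1e-9))
  p <- as.vector(unclass(f$table))
  A <- marginal_constraint_matrix(3, 3, 2)
  ns <- svd(rbind(A, 1), nv = length(p))$v[, (qr(rbind(A, 1))$rank + 1):length(p),
                                           drop = FALSE]
  h0 <- entropy(p)
  for (rep in 1:20) {
    dir <- ns %*% rnorm(ncol(ns))
    q <- p + 1e-4 * dir / sqrt(sum(dir^2))
    if (all(q > 0)) expect_lte(entropy(q / sum(q)), h0 + 1e-10)
  }
})

test_that("model distribution is gauge-invariant and uniform at zero params", {
  m0 <- groupmaxent:::new_maxent(list("1" = array(0, 3), "2" = array(0, 3)),
                                 2, 3)
  expect_equal(as.vector(unclass(m0$table)), rep(1 / 9, 9))
  set.seed(6)
  pars <- list("1" = array(rnorm(3), 3), "2" = array(rnorm(3), 3),
               "1,2" = array(rnorm(9), c(3, 3)))
  m1 <- groupmaxent:::new_maxent(pars, 2, 3)
  pars2 <- pars
  pars2[["1"]] <- pars[["1"]] + 2.5  # constant shift absorbed by partition
  m2 <- groupmaxent:::new_maxent(pars2, 2, 3)
  expect_equal(unclass(m1$table), unclass(m2$table), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m2$log_partition - m1$log_partition, 2.5, tolerance = 1e-12)
})

test_that("fit -> marginals -> refit reproduces the model distribution", {
  set.seed(7)
  d <- random_dense_dist(3, 3)
  f <- maxent(d, order = 2)
  f2 <- maxent(f$table, order = 2)
  expect_lt(js_divergence(f$table, f2$table), 1e-9)
})

test_that("zero-sum gauge parameters are centered and reproduce log p", {
  set.seed(8)
  d <- random_dense_dist(3, 3)
  f <- maxent(d, order = 2, control = maxent_control(tol = 1e-9))
  eff <- coef(f, gauge = "zero.sum")
  # each block sums to zero along every axis
  for (key in setdiff(names(eff), "(const)")) {
    e <- eff[[key]]
    if (length(dim(e)) == 1) expect_equal(sum(e), 0, tolerance = 1e-9)
    else for (ax in 1:2)
      expect_equal(max(abs(apply(e, ax, sum))), 0, tolerance = 1e-9)
  }
  # effects of order above the model order vanish (here: none fitted above 2)
  full_eff <- zero_sum_gauge(f$table)
  expect_lt(max(abs(full_eff[["1,2,3"]])), 1e-6)
  # reconstruction: sum of effects equals log2 p
  cfg <- groupmaxent:::config_grid(3, 3)
  logp <- rep(full_eff[["(const)"]], nrow(cfg))
  for (key in setdiff(names(full_eff), "(const)")) {
    sub <- groupmaxent:::key_subset(key)
    lin <- groupmaxent:::subset_linear_index(cfg, sub, 3)
    logp <- logp + as.vector(full_eff[[key]])[lin]
  }
  expect_equal(logp, as.vector(log2(unclass(f$table))), tolerance = 1e-9)
})

test_that("degenerate orders are rejected", {
  set.seed(9)
  d <- random_dense_dist(2, 3)
  expect_error(maxent(d, order = 3), class = "groupmaxent_argument_error")
  expect_error(maxent(d, order = 0), class = "groupmaxent_argument_error")
})

test_that("predict and simulate are consistent with the model table", {
  set.seed(10)
  d <- random_dense_dist(2, 4)
  f <- maxent(d, order = 2)
  cfg <- groupmaxent:::config_grid(2, 4)
  expect_equal(predict(f, cfg), as.vector(unclass(f$table)), tolerance = 1e-12)
  s1 <- simulate(f, nsim = 100, seed = 5)
  s2 <- simulate(f, nsim = 100, seed = 5)
  expect_identical(s1$states, s2$states)
})

test_that("split_train_test partitions the series reproducibly", {
  set.seed(11)
  s <- random_series(10, 2, 3)
  h <- split_train_test(s, seed = 2)
  expect_equal(nrow(h$train$states), 5L)
  expect_equal(nrow(h$test$states), 5L)
  h2 <- split_train_test(s, seed = 2)
  expect_identical(h$train$states, h2$train$states)
  # counts add up to the full counts
  full <- tabulate(groupmaxent:::config_linear_index(s$states, 3), 9)
  parts <- tabulate(groupmaxent:::config_linear_index(h$train$states, 3), 9) +
    tabulate(groupmaxent:::config_linear_index(h$test$states, 3), 9)
  expect_equal(parts, full)
})

test_that("evaluation: exact model has zero divergence and high funnel coverage", {
  set.seed(12)
  truth <- random_dense_dist(2, 3)
  m <- groupmaxent:::new_maxent(
    list("1,2" = array(log2(unclass(truth) * 9), dim = c(3, 3))), 2, 3)
  s <- simulate(m, nsim = 20000, seed = 1)
  test_d <- empirical_distribution(s)
  ev <- evaluate_model(m, test_d)
  expect_lt(ev$js_divergence, 0.005)
  expect_gte(ev$funnel_coverage, 0.9)
  # disjoint support -> divergence 1
  pm1 <- joint_distribution(array(c(1, 0, 0, 0), c(2, 2)), sample_count = 10)
  m2 <- maxent(joint_distribution(array(c(0, 0, 0, 1), c(2, 2))), order = 2)
  expect_equal(evaluate_model(m2, pm1)$js_divergence, 1)
})

test_that("decomposition: chain, additivity, and analytic cases", {
  # product distribution: everything zero
  prod_d <- joint_distribution(outer(c(0.3, 0.7), c(0.2, 0.8)))
  dec0 <- decompose(prod_d)
  expect_equal(dec0$multi_information, 0, tolerance = 1e-10)
  expect_equal(unname(dec0$contributions), 0, tolerance = 1e-10)
  # parity: I_N = 1 bit, all of it third order
  dec <- decompose(parity_distribution())
  expect_equal(dec$multi_information, 1, tolerance = 1e-12)
  expect_equal(unname(dec$contributions["I2"]), 0, tolerance = 1e-9)
  expect_equal(unname(dec$contributions["I3"]), 1, tolerance = 1e-9)
  # random distributions: non-increasing entropy chain, contributions sum to I_N
  set.seed(13)
  for (rep in 1:3) {
    d <- random_dense_dist(3, 3)
    dc <- decompose(d, control = maxent_control(tol = 1e-9))
    expect_true(all(diff(dc$entropies) <= 1e-8))
    expect_equal(sum(dc$contributions), dc$multi_information, tolerance = 1e-8)
    expect_true(all(dc$contributions >= -1e-8))
  }
})

test_that("the model-versus-data plot renders and returns the evaluation", {
  set.seed(15)
  truth <- random_dense_dist(2, 3)
  m <- maxent(truth, order = 1)
  s <- simulate(m, nsim = 5000, seed = 1)
  pdf(NULL)
  on.exit(dev.off())
  ev <- plot(m, empirical_distribution(s))
  expect_s3_class(ev, "model_evaluation")
})

test_that("model files round-trip through JSON", {
  set.seed(14)
  d <- random_dense_dist(3, 3)
  f <- maxent(d, order = 2, epsilon = 2^-10)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent(f, path)
  f2 <- read_maxent(path)
  expect_equal(unclass(f2$table), unclass(f$table), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(f2$epsilon, f$epsilon)
  expect_equal(f2$order, f$order)
  expect_equal(unlist(f2$params), unlist(f$params), tolerance = 1e-12)
  # exact zeros of the penalized fit survive the round trip
  expect_identical(unlist(f2$params) == 0, unlist(f$params) == 0)
})
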