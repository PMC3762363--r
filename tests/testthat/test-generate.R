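test_that("ground-truth models honor the spec and are reproducible", {
  spec <- generator_spec(n_animals = 3, n_zones = 4, order = 2,
                         coupling_scale = 0, session_bins = 10L, seed = 1)
  m <- ground_truth_model(spec)
  # zero coupling scale -> factorized distribution
  expect_equal(multi_information(m$table), 0, tolerance = 1e-10)
  expect_true(all(unlist(m$params[subset_order(names(m$params)) >= 2]) == 0))

  spec2 <- generator_spec(n_animals = 3, n_zones = 4, order = 2,
                          coupling_scale = 0.5, session_bins = 10L, seed = 2)
  m2a <- ground_truth_model(spec2)
  m2b <- ground_truth_model(spec2)
  expect_identical(unlist(m2a$params), unlist(m2b$params))
  # order-2 spec: no third-order block exists
  expect_false("1,2,3" %in% names(m2a$params))
  # sparse couplings with a surplus of negative values
  cp <- unlist(m2a$params[subset_order(names(m2a$params)) == 2])
  expect_gt(mean(cp == 0), 0.6)
  expect_gt(sum(cp < 0), sum(cp > 0))
})

test_that("generator spec validates its fields", {
  expect_error(generator_spec(order = 5), class = "groupmaxent_argument_error")
  expect_error(generator_spec(order = 3, coupling_scale = 0.5),
               class = "groupmaxent_argument_error")
  expect_error(generator_spec(dwell_tail_exponent = 0),
               class = "groupmaxent_argument_error")
})

test_that("synergistic model reduces to parity in the binary large-weight limit", {
  m <- synergistic_model(2, weight = 40)
  expect_equal(unclass(m$table), unclass(parity_distribution()),
               tolerance = 1e-9, ignore_attr = TRUE)
  dec <- decompose(m$table)
  expect_equal(dec$entropies[["p2"]], 3, tolerance = 1e-6)
  expect_equal(dec$multi_information, 1, tolerance = 1e-6)
  # weight 0: uniform over Z^3
  m0 <- synergistic_model(3, weight = 0)
  expect_equal(as.vector(unclass(m0$table)), rep(1 / 27, 27))
})

test_that("exact sampler frequencies match the model table (chi-square GOF)", {
  set.seed(1)
  spec <- generator_spec(n_animals = 4, n_zones = 10, order = 2,
                         coupling_scale = 0.5, session_bins = 10L, seed = 5)
  gt <- ground_truth_model(spec)
  s <- simulate(gt, nsim = 1e5, seed = 17)
  counts <- tabulate(groupmaxent:::config_linear_index(s$states, 10), 1e4)
  p <- as.vector(unclass(gt$table))
  gof <- suppressWarnings(stats::chisq.test(counts, p = p))
  expect_gt(gof$p.value, 0.01)
  # pairwise marginals converge at the multinomial rate
  emp <- marginal_set(empirical_distribution(s), 2)
  mod <- marginal_set(gt$table, 2)
  for (key in c("1,2", "2,4")) {
    dev <- abs(as.vector(emp$tables[[key]]) - as.vector(mod$tables[[key]]))
    sd_bound <- sqrt(as.vector(mod$tables[[key]]) / 1e5)
    expect_true(all(dev <= 5 * sd_bound + 1e-4))
  }
})

test_that("uniform model sampling is uniform within 5 sigma", {
  m <- groupmaxent:::new_maxent(list("1" = array(0, 4), "2" = array(0, 4)), 2, 4)
  s <- simulate(m, nsim = 1e6, seed = 3)
  f <- tabulate(groupmaxent:::config_linear_index(s$states, 4), 16) / 1e6
  sigma <- sqrt((1 / 16) * (15 / 16) / 1e6)
  expect_true(all(abs(f - 1 / 16) < 5 * sigma))
})

test_that("gibbs dialect is stationary: long runs reproduce the model law", {
  spec <- generator_spec(n_animals = 3, n_zones = 3, order = 2,
                         coupling_scale = 0.6, session_bins = 150000L, seed = 7)
  gt <- ground_truth_model(spec)
  s <- sample_markov_series(gt, spec, dialect = "gibbs")
  expect_lt(js_divergence(empirical_distribution(s), gt$table), 0.005)
  # independence by construction at zero coupling
  spec0 <- generator_spec(n_animals = 3, n_zones = 3, order = 2,
                          coupling_scale = 0, session_bins = 60000L, seed = 8)
  s0 <- sample_markov_series(ground_truth_model(spec0), spec0, dialect = "gibbs")
  expect_lt(information_fraction(s0, 1, c(2, 3)), 0.02)
  expect_error(sample_markov_series(gt, spec, dialect = "bogus"))
})

test_that("semi-markov dwell times have the requested power-law tail", {
  spec <- generator_spec(n_animals = 3, n_zones = 4, order = 2,
                         coupling_scale = 0.3, dwell_tail_exponent = 2,
                         session_bins = 120000L, seed = 9)
  gt <- ground_truth_model(spec)
  s <- sample_markov_series(gt, spec, dialect = "semi-markov")
  dw <- unlist(dwell_times(s, 1)) / s$bin_duration
  dd <- 5:200
  surv <- vapply(dd, function(d) mean(dw >= d), numeric(1))
  keep <- surv > 0
  slope <- stats::coef(stats::lm(log(surv[keep]) ~ log(dd[keep])))[2]
  expect_lt(abs(slope + spec$dwell_tail_exponent), 0.8)
})

test_that("cohorts are reproducible, distinct across seeds, and read back losslessly", {
  specs <- list(generator_spec(3, 3, 2, 0.4, session_bins = 500L, seed = 11),
                generator_spec(3, 3, 2, 0.4, session_bins = 500L, seed = 12))
  ch <- make_cohort(specs)
  expect_length(ch$series, 2)
  expect_false(identical(ch$series[[1]]$states, ch$series[[2]]$states))
  ch2 <- make_cohort(specs)
  expect_identical(ch$series[[1]]$states, ch2$series[[1]]$states)
  # I/O round trip through the state-space module
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(ch$series[[1]], path)
  back <- read_series(path, n_zones = 3)
  expect_identical(unname(back$states), unname(ch$series[[1]]$states))
  # cohort with no interactions: multi-information within noise of zero
  specs0 <- list(generator_spec(3, 3, 2, 0, session_bins = 50000L, seed = 13))
  ch0 <- make_cohort(specs0)
  expect_lt(multi_information(empirical_distribution(ch0$series[[1]])), 0.01)
})

test_that("shuffling animals preserves marginals and kills correlations", {
  spec <- generator_spec(3, 3, 2, 0.8, session_bins = 50000L, seed = 14)
  gt <- ground_truth_model(spec)
  s <- simulate(gt, nsim = 50000, seed = 15)
  sh <- shuffle_animals(s, seed = 16)
  for (a in 1:3)
    expect_equal(occupancy_histogram(sh, a), occupancy_histogram(s, a))
  expect_lt(multi_information(empirical_distribution(sh)), 0.01)
})
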