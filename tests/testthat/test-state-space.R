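test_that("series files round-trip and are validated against the legend", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("m1,m2,m3,m4", "1,1,2,2", "1,1,2,2", "3,3,3,3"), path)
  s <- read_series(path, legend = zone_legend(paste0("z", 1:10)))
  expect_equal(dim(s), c(3L, 4L))
  expect_equal(s$n_zones, 10L)
  expect_equal(s$states[3, ], c(m1 = 3L, m2 = 3L, m3 = 3L, m4 = 3L))

  # out-of-range code
  writeLines(c("m1,m2", "1,11"), path)
  expect_error(read_series(path, legend = zone_legend(paste0("z", 1:10))),
               "out of range", class = "groupmaxent_validation_error")
  # malformed row reported with its line number
  writeLines(c("m1,m2", "1,2", "1"), path)
  expect_error(read_series(path, n_zones = 3), "line 3",
               class = "groupmaxent_parse_error")
  # non-integer code
  writeLines(c("m1,m2", "1,x"), path)
  expect_error(read_series(path, n_zones = 3), "non-integer",
               class = "groupmaxent_parse_error")

  # write/read identity, tab + time column dialects
  set.seed(4)
  s0 <- random_series(200, 3, 5)
  for (tc in c(FALSE, TRUE)) {
    write_series(s0, path, sep = if (tc) "\t" else ",", time_column = tc)
    s1 <- read_series(path, n_zones = 5)
    expect_identical(unname(s1$states), unname(s0$states))
    if (tc) expect_equal(s1$bin_duration, s0$bin_duration)
  }
})

test_that("legend files round-trip and enforce contiguous 1-based codes", {
  path <- withr::local_tempfile()
  lg <- zone_legend(c("open field", "water", "nest"))
  write_legend(lg, path)
  expect_identical(unclass(read_legend(path)), unclass(lg))
  writeLines(c("1,a", "3,b"), path)
  expect_error(read_legend(path), "contiguous",
               class = "groupmaxent_parse_error")
  expect_error(zone_legend(c("a", "a")), "unique")
})

test_that("rebinning takes the modal zone, breaking ties by earliest frame", {
  # 25 frames/s rebinned to 240 ms: factor 6
  set.seed(11)
  s <- random_series(6 * 1000, 2, 4, bin_duration = 0.04)
  r <- rebin(s, 0.24)
  expect_equal(nrow(r$states), 1000L)
  expect_equal(r$bin_duration, 0.24)
  # constant series unchanged at any factor
  cs <- config_series(matrix(2L, 30, 2), bin_duration = 0.04, n_zones = 3)
  expect_true(all(rebin(cs, 0.12)$states == 2L))
  # 3-3 tie: [1,1,1,2,2,2] -> zone 1 (earliest)
  ts <- config_series(matrix(c(1, 1, 1, 2, 2, 2), ncol = 1), bin_duration = 1,
                      n_zones = 2)
  expect_equal(as.integer(rebin(ts, 6)$states), 1L)
  # tie where the later-coded zone comes first: [2,1,2,1] -> zone 2
  ts2 <- config_series(matrix(c(2, 1, 2, 1), ncol = 1), bin_duration = 1,
                       n_zones = 2)
  expect_equal(as.integer(rebin(ts2, 4)$states), 2L)
  expect_error(rebin(s, 0.1), "integer multiple",
               class = "groupmaxent_argument_error")
})

test_that("empirical distribution counts configurations and keeps marginals", {
  # T=4 with states A,A,B,C
  s <- config_series(rbind(c(1, 1), c(1, 1), c(2, 1), c(2, 2)), n_zones = 2)
  d <- empirical_distribution(s)
  expect_equal(as.vector(unclass(d)), c(0.5, 0.25, 0, 0.25))
  expect_equal(sum(unclass(d)), 1)
  expect_equal(sample_count(d), 4L)

  set.seed(21)
  s2 <- random_series(500, 3, 4)
  d2 <- empirical_distribution(s2)
  expect_lte(sum(unclass(d2) > 0), min(500, 4^3))
  # marginals of every order equal directly counted marginals
  ms <- marginal_set(d2, 3)
  for (key in names(ms$tables)) {
    sub <- groupmaxent:::key_subset(key)
    lin <- groupmaxent:::subset_linear_index(s2$states, sub, 4)
    direct <- tabulate(lin, nbins = 4^length(sub)) / nrow(s2$states)
    expect_equal(as.vector(ms$tables[[key]]), direct, tolerance = 1e-12)
  }
  # occupancy histogram equals the single-animal marginal
  expect_equal(unname(occupancy_histogram(s2, 2)),
               as.vector(ms$tables[["2"]]))
  # rebin-invariance for a series constant within bins
  blocky <- config_series(s2$states[rep(seq_len(100), each = 4), ],
                          bin_duration = 0.06, n_zones = 4)
  d_fine <- empirical_distribution(blocky)
  d_coarse <- empirical_distribution(rebin(blocky, 0.24))
  expect_equal(unclass(d_coarse), unclass(d_fine), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("occupancy histogram approaches uniform on uniform random data", {
  set.seed(31)
  t_bins <- 40000; z <- 5
  s <- random_series(t_bins, 2, z)
  h <- occupancy_histogram(s, 1)
  sigma <- sqrt((1 / z) * (1 - 1 / z) / t_bins)
  expect_true(all(abs(h - 1 / z) < 3.5 * sigma))
  expect_error(occupancy_histogram(s, 3), class = "groupmaxent_argument_error")
})

test_that("dwell times run-length encode visits and conserve total time", {
  s <- config_series(matrix(c(1, 1, 1, 2, 2, 1), ncol = 1), bin_duration = 0.24,
                     n_zones = 2)
  dw <- dwell_times(s, 1)
  expect_equal(dw[[1]], c(0.72, 0.24))
  expect_equal(dw[[2]], 0.48)
  set.seed(41)
  s2 <- random_series(3000, 2, 6)
  expect_equal(sum(unlist(dwell_times(s2, 2))), 3000 * 0.24)
})

test_that("rank-frequency is sorted and counts occupied states", {
  d <- joint_distribution(array(1 / 8, dim = c(2, 2, 2)))
  rf <- rank_frequency(d)
  expect_equal(rf$occupied, 8)
  expect_equal(rf$probability, rep(1 / 8, 8))
  set.seed(51)
  rf2 <- rank_frequency(random_dense_dist(3, 3))
  expect_true(all(diff(rf2$probability) <= 0))
})

test_that("expected distinct states: closed form matches Monte-Carlo", {
  # point mass
  pm <- joint_distribution(array(c(1, 0, 0, 0), dim = c(2, 2)))
  r <- expected_distinct_states(pm, n = 50, seed = 1, reps = 5)
  expect_equal(r$expected, 1)
  expect_equal(r$mc_mean, 1)
  # uniform over K states with n >> K log K
  u <- joint_distribution(array(1 / 16, dim = c(4, 4)))
  r2 <- expected_distinct_states(u, n = 500, seed = 2, reps = 10)
  expect_equal(r2$expected, 16, tolerance = 1e-6)
  # Monte-Carlo mean near closed form on a skewed table
  set.seed(61)
  d <- random_dense_dist(2, 5)
  r3 <- expected_distinct_states(d, n = 40, seed = 3, reps = 400)
  expect_lt(abs(r3$mc_mean - r3$expected), 3 * r3$mc_sd / sqrt(400))
})

test_that("distribution files round-trip sparsely and byte-stably", {
  set.seed(71)
  s <- random_series(300, 3, 3)
  d <- empirical_distribution(s)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_distribution(d, p1)
  d2 <- read_distribution(p1)
  expect_equal(unclass(d2), unclass(d), tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(sample_count(d2), 300L)
  write_distribution(d2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("non-enumerable state spaces are refused with a capability error", {
  s <- config_series(matrix(sample.int(10, 8 * 20, TRUE), ncol = 8),
                     n_zones = 10)
  expect_error(empirical_distribution(s), "guard",
               class = "groupmaxent_capability_error")
})

test_that("series constructor rejects gaps and bad codes", {
  expect_error(config_series(matrix(c(1, NA), 2, 1), n_zones = 2), "missing")
  expect_error(config_series(matrix(c(1, 3), 2, 1), n_zones = 2), "out of range")
  expect_error(config_series(matrix(1.5, 2, 1), n_zones = 2), "integer")
})
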