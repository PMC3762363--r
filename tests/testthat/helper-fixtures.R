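# Fixtures built in code: analytic distributions and small random instances.

# Exact parity (XOR) distribution for 3 binary-zone animals: uniform over the
# 4 even-parity states. All single and pairwise marginals are uniform, yet
# any animal is a deterministic function of the other two.
parity_distribution <- function() {
  cfg <- groupmaxent:::config_grid(3L, 2L)
  p <- as.numeric(rowSums(cfg) %% 2L == 0L) / 4
  joint_distribution(array(p, dim = c(2, 2, 2)))
}

# A series whose empirical distribution is exactly the parity distribution.
parity_series <- function() {
  cfg <- groupmaxent:::config_grid(3L, 2L)
  config_series(cfg[rowSums(cfg) %% 2L == 0L, , drop = FALSE],
                bin_duration = 0.24, n_zones = 2)
}

# Random dense joint distribution (Dirichlet(1) over all Z^N states).
random_dense_dist <- function(n_animals, n_zones) {
  g <- stats::rgamma(n_zones^n_animals, shape = 1)
  joint_distribution(array(g / sum(g), dim = rep(n_zones, n_animals)))
}

random_series <- function(t_bins, n_animals, n_zones, bin_duration = 0.24) {
  config_series(matrix(sample.int(n_zones, t_bins * n_animals, replace = TRUE),
                       ncol = n_animals),
                bin_duration = bin_duration, n_zones = n_zones)
}

subset_order <- function(keys) lengths(lapply(keys, groupmaxent:::key_subset))
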