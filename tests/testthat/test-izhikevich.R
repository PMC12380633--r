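test_that("a driven single neuron spikes tonically, matching the reference update", {
  cfg <- izhikevich_config(n_neurons = 1, T_ms = 5000, dt_ms = 0.5,
                           mu_ext = 10, sigma_ext = 0, seed = 1)
  raster <- simulate_izhikevich(matrix(0, 1, 1), cfg)
  got <- sum(raster$spikes)
  ref <- loop_izhikevich_neuron(I = 10, dt = 0.5, steps = 1e4)
  ## rates agree to within one spike per second
  expect_lt(abs(got - ref) / 5, 1)
  expect_gt(got, 10)  # tonic firing
})

test_that("an undriven network is silent", {
  cfg <- izhikevich_config(n_neurons = 20, T_ms = 1000, mu_ext = 0,
                           sigma_ext = 0, seed = 1)
  raster <- simulate_izhikevich(matrix(0, 20, 20), cfg)
  expect_equal(sum(raster$spikes), 0)
})

test_that("connectivity density follows base_sparsity x exp(-lambda d)", {
  g <- place_neurons(400, seed = 8)
  cfg0 <- izhikevich_config(n_neurons = 400, lambda = 1e-12)
  J0 <- build_izhikevich_network(g, cfg0, seed = 2)
  dens <- mean(J0[row(J0) != col(J0)] > 0)
  se <- sqrt(0.1 * 0.9 / (400 * 399))
  expect_lt(abs(dens - 0.1), 3 * se)

  cfg5 <- izhikevich_config(n_neurons = 400, lambda = 5)
  J5 <- build_izhikevich_network(g, cfg5, seed = 2)
  d <- g$distances[row(g$distances) != col(g$distances)]
  conn <- J5[row(J5) != col(J5)] > 0
  for (b in list(c(0, 0.2), c(0.2, 0.5), c(0.5, 1))) {
    sel <- d >= b[1] & d < b[2]
    p_exp <- mean(0.1 * exp(-5 * d[sel]))
    se <- sqrt(p_exp * (1 - p_exp) / sum(sel))
    expect_lt(abs(mean(conn[sel]) - p_exp), 3.5 * se + 1e-4)
  }

  expect_error(build_izhikevich_network(
    g, izhikevich_config(n_neurons = 400, base_sparsity = 0)),
    "disconnected")
})

test_that("default-network statistics are near-Poisson with weak correlations", {
  cfg <- izhikevich_config(n_neurons = 400, T_ms = 2e4, seed = 5)
  sim <- simulate_izhikevich_network(cfg)
  d <- raster_diagnostics(sim$raster, count_bin_ms = 10)
  expect_gt(d$mean_rate_hz$population, 1)
  expect_lt(d$mean_rate_hz$population, 12)
  expect_gt(d$mean_fano, 0.7)
  expect_lt(d$mean_fano, 1.3)
  ## weak-coupling regime: small positive mean correlation
  expect_gt(d$mean_pairwise_correlation, 0)
  expect_lt(d$mean_pairwise_correlation, 0.05)
})

test_that("halving the integration step changes the rate by less than 5 percent", {
  rate_at <- function(dt) {
    cfg <- izhikevich_config(n_neurons = 200, T_ms = 1e4, dt_ms = dt, seed = 6)
    sim <- simulate_izhikevich_network(cfg)
    sum(sim$raster$spikes) / 200 / 10
  }
  r50 <- rate_at(0.5)
  r25 <- rate_at(0.25)
  expect_lt(abs(r25 - r50) / r50, 0.05)
})

test_that("broad connectivity (small lambda) synchronises the network", {
  cfg <- izhikevich_config(n_neurons = 300, T_ms = 1e4, seed = 4)
  tab <- lambda_sweep_correlations(c(1, 5), cfg)
  expect_gt(tab$mean_corr[tab$lambda == 1], tab$mean_corr[tab$lambda == 5])

  single <- lambda_sweep_correlations(5, cfg)
  expect_true(is.na(attr(single, "transition_lambda")))
  expect_error(lambda_sweep_correlations(numeric(0), cfg), "empty")
  expect_error(lambda_sweep_correlations(c(5, 1), cfg), "increasing")
})

test_that("weight shuffling destroys the short- vs long-range correlation gap", {
  cfg <- izhikevich_config(n_neurons = 300, T_ms = 1e4, seed = 4)
  spatial <- lambda_sweep_correlations(4, cfg)
  shuffled <- lambda_sweep_correlations(4, cfg, shuffle = TRUE)
  gap_s <- abs(spatial$short_range_corr - spatial$long_range_corr)
  gap_r <- abs(shuffled$short_range_corr - shuffled$long_range_corr)
  expect_gt(gap_s, gap_r)
})
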