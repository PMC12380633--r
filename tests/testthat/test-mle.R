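test_that("raster-only log-likelihood equals the brute-force triple loop", {
  S <- toy_raster_matrix()
  g <- toy_geometry()
  for (lam in c(0.5, 2, 8)) {
    k <- decay_kernel("exponential", lambda = lam)
    W <- kernel_weight(k, g$distances); diag(W) <- 0
    for (lag in 0:1) {
      expect_equal(raster_loglik(spike_raster(S), g, k, lag = lag),
                   loop_raster_loglik(S, W, lag = lag), tolerance = 1e-10)
    }
  }

  set.seed(21)
  for (rep in 1:4) {
    n <- sample(3:10, 1)
    S <- matrix(rbinom(n * 50, 1, 0.15), n, 50)
    g <- place_neurons(n, seed = rep)
    k <- decay_kernel("half_gaussian", sigma = 0.4)
    W <- kernel_weight(k, g$distances); diag(W) <- 0
    expect_equal(raster_loglik(spike_raster(S), g, k),
                 loop_raster_loglik(S, W), tolerance = 1e-10)
  }
})

test_that("an all-zero raster gives a near-zero, flagged log-likelihood", {
  g <- place_neurons(4, seed = 1)
  r <- spike_raster(matrix(0, 4, 100))
  expect_warning(ll <- raster_loglik(r, g, decay_kernel("exponential", lambda = 5)),
                 "uninformative")
  expect_equal(ll, 4 * 100 * log1p(-1e-10), tolerance = 1e-12)
  expect_error(estimate_decay(r, g), "silent")
})

test_that("known-model gradient matches finite differences and vanishes with coupling", {
  set.seed(5)
  S <- matrix(rbinom(8 * 60, 1, 0.2), 8, 60)
  r <- spike_raster(S)
  g <- place_neurons(8, seed = 5)

  for (lam in c(1, 4)) {
    out <- known_model_loglik_and_gradient(r, g, r0 = -2, alpha = 0.5,
                                           lambda = lam)
    h <- 1e-6
    fd <- (known_model_loglik_and_gradient(r, g, -2, 0.5, lam + h)$loglik -
           known_model_loglik_and_gradient(r, g, -2, 0.5, lam - h)$loglik) /
      (2 * h)
    expect_equal(out$gradient, fd, tolerance = 1e-5)
  }

  out0 <- known_model_loglik_and_gradient(r, g, r0 = -2, alpha = 0,
                                          lambda = 3)
  expect_equal(out0$gradient, 0)
})

test_that("the profile estimator is deterministic, respects bounds, and flags boundaries", {
  cfg <- poisson_net_config(n_neurons = 100, T_ms = 5000, seed = 2)
  sim <- simulate_poisson_network(cfg)
  f1 <- estimate_decay(sim$raster, sim$geom, grid_size = 10)
  f2 <- estimate_decay(sim$raster, sim$geom, grid_size = 10)
  expect_identical(f1$estimate, f2$estimate)
  expect_gte(f1$estimate, f1$bounds[1])
  expect_lte(f1$estimate, f1$bounds[2])
  expect_gte(f1$loglik, max(f1$profile$loglik))

  expect_error(estimate_decay(sim$raster, sim$geom, bounds = c(5, 1)),
               "lower < upper")
  expect_error(estimate_decay(sim$raster, sim$geom,
                              likelihood = "poisson_model"), "r0")
})

test_that("the known-model likelihood recovers the generating decay", {
  ## logistic generative model; matched likelihood profile
  cfg <- poisson_net_config(n_neurons = 250, T_ms = 3e4, r0 = -6, alpha = 0.4,
                            link = "logistic",
                            kernel = decay_kernel("exponential", lambda = 5),
                            seed = 8)
  sim <- simulate_poisson_network(cfg)
  f <- estimate_decay(sim$raster, sim$geom, grid_size = 12,
                      likelihood = "poisson_model", r0 = -6, alpha = 0.4)
  expect_lt(abs(f$estimate - 5) / 5, 0.25)
  expect_false(f$boundary)
})

test_that("recovery tracks the generating decay across its range", {
  ests <- vapply(c(2, 5, 9), function(lt) {
    cfg <- poisson_net_config(n_neurons = 250, T_ms = 3e4, r0 = -6,
                              alpha = 0.4, link = "logistic",
                              kernel = decay_kernel("exponential", lambda = lt),
                              seed = 31)
    sim <- simulate_poisson_network(cfg)
    estimate_decay(sim$raster, sim$geom, grid_size = 12,
                   likelihood = "poisson_model", r0 = -6,
                   alpha = 0.4)$estimate
  }, numeric(1))
  expect_lt(median(abs(ests - c(2, 5, 9)) / c(2, 5, 9)), 0.25)
  expect_true(all(diff(ests) > 0))  # monotone in the truth
})

test_that("stability analysis returns the full fit and shrinking dispersion", {
  cfg <- poisson_net_config(n_neurons = 120, T_ms = 8000, r0 = -6,
                            alpha = 0.8, link = "logistic", seed = 13)
  sim <- simulate_poisson_network(cfg)
  st <- stability_curves(sim$raster, sim$geom,
                         neuron_subset_sizes = c(120),
                         time_prefixes_ms = 8000,
                         n_repeats = 2, seed = 1, grid_size = 8,
                         likelihood = "poisson_model", r0 = -6, alpha = 0.8)
  full_est <- st$estimate[st$kind == "full"]
  expect_equal(st$estimate[st$kind == "neurons" & st$size == 120], full_est)
  expect_equal(st$estimate[st$kind == "time" & st$size == 8000], full_est)
  expect_error(stability_curves(sim$raster, sim$geom,
                                neuron_subset_sizes = 1), ">= 2")
  expect_error(stability_curves(sim$raster, sim$geom,
                                time_prefixes_ms = 1e9), "outside")
})
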