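test_that("GLM log-likelihood matches closed form at zero coupling and the loop oracle", {
  S <- toy_raster_matrix()
  g <- toy_geometry()
  r <- spike_raster(S)
  k <- decay_kernel("exponential", lambda = 3)

  ## alpha = 0: Bernoulli LL from the spike count alone (bins 2..T)
  r0 <- -1.2
  S2 <- S[, -1]
  ll0 <- sum(S2 * log(plogis(r0)) + (1 - S2) * log(1 - plogis(r0)))
  expect_equal(glm_loglik(r, g, k, r0, 0), ll0, tolerance = 1e-10)

  ## lambda enters only through alpha
  k2 <- decay_kernel("exponential", lambda = 17)
  expect_equal(glm_loglik(r, g, k, r0, 0), glm_loglik(r, g, k2, r0, 0))

  ## literal loop transcription
  W <- kernel_weight(k, g$distances); diag(W) <- 0
  expect_equal(glm_loglik(r, g, k, -0.5, 0.8),
               loop_glm_loglik(S, W, -0.5, 0.8), tolerance = 1e-10)
})

test_that("all three analytic gradients match central finite differences", {
  set.seed(17)
  S <- matrix(rbinom(7 * 80, 1, 0.25), 7, 80)
  r <- spike_raster(S)
  g <- place_neurons(7, seed = 17)

  for (fam in c("exponential", "half_gaussian", "inverse_square")) {
    theta <- switch(fam, exponential = 3, half_gaussian = 0.4,
                    inverse_square = 0.5)
    mk <- function(th) {
      if (fam == "exponential") decay_kernel(fam, lambda = th)
      else decay_kernel(fam, sigma = th)
    }
    r0 <- -1.5; alpha <- 0.6
    gr <- glm_gradients(r, g, mk(theta), r0, alpha)
    h <- 1e-6
    fd_r0 <- (glm_loglik(r, g, mk(theta), r0 + h, alpha) -
              glm_loglik(r, g, mk(theta), r0 - h, alpha)) / (2 * h)
    fd_a <- (glm_loglik(r, g, mk(theta), r0, alpha + h) -
             glm_loglik(r, g, mk(theta), r0, alpha - h)) / (2 * h)
    fd_t <- (glm_loglik(r, g, mk(theta + h), r0, alpha) -
             glm_loglik(r, g, mk(theta - h), r0, alpha)) / (2 * h)
    expect_equal(unname(gr["r0"]), fd_r0, tolerance = 1e-5)
    expect_equal(unname(gr["alpha"]), fd_a, tolerance = 1e-5)
    expect_equal(unname(gr["theta"]), fd_t, tolerance = 1e-5)
  }
})

test_that("gradient signs behave at the edges", {
  g <- place_neurons(4, seed = 2)
  ## alpha = 0: decay gradient identically zero
  r <- spike_raster(matrix(rbinom(4 * 30, 1, 0.3), 4, 30))
  gr <- glm_gradients(r, g, decay_kernel("exponential", lambda = 2), -1, 0)
  expect_equal(unname(gr["theta"]), 0)

  ## saturated raster: baseline gradient positive (model under-predicts)
  sat <- spike_raster(matrix(1, 4, 30))
  gr2 <- glm_gradients(sat, g, decay_kernel("exponential", lambda = 2), 0, 0)
  expect_gt(unname(gr2["r0"]), 0)
})

test_that("the spatial GLM recovers generating parameters from logistic data", {
  cfg <- poisson_net_config(n_neurons = 250, T_ms = 3e4, r0 = -6, alpha = 0.4,
                            link = "logistic",
                            kernel = decay_kernel("exponential", lambda = 5),
                            seed = 19)
  sim <- simulate_poisson_network(cfg)
  fit <- fit_spatial_glm(sim$raster, sim$geom, grid_size = 10)
  expect_true(fit$converged)
  expect_lt(abs(fit$r0 - (-6)) / 6, 0.15)
  expect_lt(abs(fit$alpha - 0.4) / 0.4, 0.3)
  expect_lt(abs(fit$estimate - 5) / 5, 0.3)
  ## accepted profile: reported optimum at least as good as every grid point
  expect_gte(fit$loglik, max(fit$profile$loglik))
})

test_that("uncoupled data carry no interaction evidence", {
  set.seed(23)
  S <- matrix(rbinom(60 * 4000, 1, 0.005), 60, 4000)
  g <- place_neurons(60, seed = 23)
  fit <- fit_spatial_glm(spike_raster(S), g, grid_size = 6)
  ## improvement over the intercept-only model stays within chance for one
  ## extra parameter (or the coupling is clamped to zero outright)
  S2 <- S[, -1]
  p0 <- mean(S2)
  ll_null <- sum(S2) * log(p0) + sum(1 - S2) * log(1 - p0)
  expect_true(fit$flag == "alpha_zero" || fit$loglik - ll_null < 8)
})
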