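test_that("kernel weights match closed-form values", {
  expect_equal(kernel_weight(decay_kernel("exponential", lambda = 5), 0), 1)
  expect_equal(kernel_weight(decay_kernel("exponential", lambda = 5), 0.2),
               exp(-1), tolerance = 1e-12)
  k_lin <- decay_kernel("linear", sigma = 1)
  expect_equal(kernel_weight(k_lin, 0.3), 0.7)
  expect_equal(kernel_weight(k_lin, 2), 0)  # clipped, not negative
  expect_equal(kernel_weight(decay_kernel("inverse_square", sigma = 1), 0), 1)
  expect_equal(kernel_weight(decay_kernel("half_gaussian", sigma = 0.5), 0), 1)
})

test_that("connection probability follows the exponential rule", {
  expect_equal(connection_probability(5, 0), 1)
  expect_equal(connection_probability(0, 2.7), 1)
  expect_equal(connection_probability(5, 1), exp(-5), tolerance = 1e-12)
  expect_error(connection_probability(-1, 1), "nonnegative")
  expect_error(connection_probability(5, -0.1), "nonnegative")
})

test_that("invalid kernel parameters are rejected", {
  expect_error(decay_kernel("exponential", lambda = 0), "positive")
  expect_error(decay_kernel("half_gaussian", sigma = -1), "positive")
  expect_error(decay_kernel("exponential"), "needs parameter")
  expect_error(decay_kernel("lognormal", sigma = 1), "mu")
  expect_error(kernel_weight(decay_kernel("exponential", lambda = 1), -1),
               "nonnegative")
})

test_that("every family is non-increasing in distance (past the lognormal mode)", {
  kernels <- list(decay_kernel("exponential", lambda = 3),
                  decay_kernel("half_gaussian", sigma = 0.4),
                  decay_kernel("linear", sigma = 2),
                  decay_kernel("inverse_square", sigma = 0.3),
                  decay_kernel("lognormal", sigma = 0.8, mu = -1))
  for (k in kernels) {
    d <- seq(0.01, 2, by = 0.01)
    w <- kernel_weight(k, d)
    if (k$family == "lognormal") {
      mode_i <- which.max(w)
      w <- w[mode_i:length(w)]
    }
    expect_true(all(diff(w) <= 1e-12), info = k$family)
  }
})

test_that("exponential kernel is memoryless and vectorisation is exact", {
  k <- decay_kernel("exponential", lambda = 2.5)
  d1 <- c(0.1, 0.4, 1.2); d2 <- c(0.3, 0.05, 0.7)
  expect_equal(kernel_weight(k, d1 + d2),
               kernel_weight(k, d1) * kernel_weight(k, d2), tolerance = 1e-12)

  set.seed(1)
  D <- matrix(runif(16, 0, 2), 4, 4)
  for (k in list(decay_kernel("half_gaussian", sigma = 0.3),
                 decay_kernel("linear", sigma = 1.2),
                 decay_kernel("inverse_square", sigma = 0.6))) {
    W <- kernel_weight(k, D)
    expect_equal(dim(W), dim(D))
    expect_equal(as.vector(W),
                 vapply(as.vector(D), function(d) kernel_weight(k, d),
                        numeric(1)), tolerance = 1e-12)
  }
})

test_that("lognormal kernel is undefined at zero distance and mu is fixed from mean log distance", {
  k <- decay_kernel("lognormal", sigma = 1, mu = 0)
  expect_warning(w0 <- kernel_weight(k, 0), "undefined")
  expect_equal(w0, 0)

  ## equilateral triangle, side 1 mm: mean log distance = 0
  g1 <- pairwise_distances(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  expect_equal(fix_lognormal_mu(g1), 0, tolerance = 1e-12)

  ## equilateral, side e: mean log distance = 1
  ge <- pairwise_distances(exp(1) * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  expect_equal(fix_lognormal_mu(ge), 1, tolerance = 1e-12)

  set.seed(3)
  pos <- cbind(runif(5), runif(5))
  g <- pairwise_distances(pos)
  d <- loop_distances(pos)
  expect_equal(fix_lognormal_mu(g),
               mean(log(d[row(d) != col(d)])), tolerance = 1e-12)

  gdup <- pairwise_distances(rbind(c(0, 0), c(0, 0), c(1, 1)))
  expect_error(fix_lognormal_mu(gdup), "coincident")
})
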