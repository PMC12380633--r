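test_that("transfer entropy: closed forms, enumeration oracle, independence", {
  ## perfect one-step copy: TE = binary entropy of the source rate
  set.seed(2)
  T <- 3e4; p <- 0.3
  x <- rbinom(T, 1, p)
  y <- c(0L, x[-T])
  r <- spike_raster(rbind(x, y))
  M <- transfer_entropy_matrix(r)$matrix
  H03 <- -(p * log2(p) + (1 - p) * log2(1 - p))  # 0.8813 bits
  expect_equal(M[1, 2], H03, tolerance = 0.02)
  ## reverse direction carries far less information
  expect_lt(M[2, 1], 0.05)

  ## independent pair: TE is estimator bias only, shrinking with T
  set.seed(3)
  a <- rbinom(2e4, 1, 0.1); b <- rbinom(2e4, 1, 0.1)
  Mi <- transfer_entropy_matrix(spike_raster(rbind(a, b)))$matrix
  expect_lt(Mi[1, 2], 5e-4)

  ## brute-force enumeration over the 8 binary states on a toy raster
  set.seed(4)
  S <- matrix(rbinom(3 * 400, 1, 0.3), 3, 400)
  Mt <- transfer_entropy_matrix(spike_raster(S))$matrix
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_equal(Mt[i, j], loop_te(S[i, ], S[j, ]), tolerance = 1e-10)
  }

  expect_error(transfer_entropy_matrix(spike_raster(matrix(0, 2, 2))),
               "too short")
})

test_that("Granger causality detects directed coupling and respects nesting", {
  ## y drives x with a 10 ms lag
  set.seed(6)
  T <- 4e4
  y <- rbinom(T, 1, 0.02)
  px <- 0.01 + 0.35 * c(rep(0, 10), y[1:(T - 10)])
  x <- rbinom(T, 1, pmin(px, 1))
  r <- spike_raster(rbind(x, y))
  M <- granger_matrix(r, bin_ms = 10, history_ms = 100)$matrix
  expect_gt(M[2, 1], M[1, 2])
  expect_gt(M[2, 1], 0.01)

  ## independent pair: both directions within the nested-model
  ## overfitting bias (about k extra parameters / 2|L_reduced|)
  set.seed(7)
  r2 <- spike_raster(rbind(rbinom(2e4, 1, 0.02), rbinom(2e4, 1, 0.02)))
  M2 <- granger_matrix(r2, bin_ms = 10, history_ms = 100)$matrix
  expect_lt(max(abs(M2), na.rm = TRUE), 0.02)

  ## silent target flagged
  r3 <- spike_raster(rbind(rbinom(5000, 1, 0.05), rep(0L, 5000)))
  g3 <- granger_matrix(r3, bin_ms = 10, history_ms = 50)
  expect_true(2 %in% attr(g3, "silent_targets"))
  expect_true(is.na(g3$matrix[1, 2]))
})

test_that("spike-count correlations match hand values and the two-pass loop", {
  x <- rep(c(1L, 0L), 50)
  same <- spike_raster(rbind(x, x))
  M <- correlation_matrix(same, bin_ms = 1)$matrix
  expect_equal(M[1, 2], 1)

  opp <- spike_raster(rbind(x, 1L - x))
  expect_equal(correlation_matrix(opp, bin_ms = 1)$matrix[1, 2], -1)

  set.seed(8)
  S <- matrix(rbinom(4 * 600, 1, 0.2), 4, 600)
  Mc <- correlation_matrix(spike_raster(S), bin_ms = 10)$matrix
  counts <- sapply(seq(1, 600, by = 10), function(s) rowSums(S[, s:(s + 9)]))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(Mc[i, j], loop_pearson(counts[i, ], counts[j, ]),
                 tolerance = 1e-10)
  }
  expect_equal(Mc, t(Mc))
  expect_error(correlation_matrix(spike_raster(matrix(0, 2, 15)), bin_ms = 10),
               "two counting bins")
})

test_that("least-squares decay fits recover known curves and flag degeneracy", {
  set.seed(9)
  g <- place_neurons(40, seed = 9)
  d <- g$distances

  exact <- pairwise_measure(1 * exp(-5 * d), "TE", list())
  f <- fit_decay_to_pairwise(exact, g)
  expect_equal(f$lambda, 5, tolerance = 1e-4)
  expect_equal(f$a, 1, tolerance = 1e-4)

  noisy_vals <- 0.4 * exp(-2.5 * d) + matrix(rnorm(1600, 0, 0.01), 40, 40)
  noisy <- pairwise_measure(noisy_vals, "correlation", list())
  fn <- fit_decay_to_pairwise(noisy, g)
  expect_lt(abs(fn$lambda - 2.5) / 2.5, 0.1)

  flat <- pairwise_measure(matrix(0.3, 40, 40), "TE", list())
  ff <- fit_decay_to_pairwise(flat, g)
  expect_equal(ff$flag, "non_identifiable")

  expect_equal(estimation_error(5, 3.5), 1.5)
  expect_equal(estimation_error(5, 5), 0)
})

test_that("pairwise budgets subsample ordered pairs deterministically", {
  set.seed(10)
  S <- matrix(rbinom(8 * 2000, 1, 0.1), 8, 2000)
  r <- spike_raster(S)
  m1 <- transfer_entropy_matrix(r, max_pairs = 20, seed = 3)$matrix
  m2 <- transfer_entropy_matrix(r, max_pairs = 20, seed = 3)$matrix
  expect_identical(m1, m2)
  expect_equal(sum(is.finite(m1)), 20)
})
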