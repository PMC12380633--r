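## Independent brute-force oracles: literal, slow transcriptions of the
## formulas, kept free of any package internals so they can certify the
## fast implementations on small instances.

## Euclidean distances by explicit double loop
loop_distances <- function(pos) {
  n <- nrow(pos)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sqrt(sum((pos[i, ] - pos[j, ])^2))
  }
  d
}

## raster-only Bernoulli log-likelihood, triple loop:
## P_i(t) = clip(sum_{j != i} S_j(t - lag) * W[i, j] / N, eps, 1 - eps)
loop_raster_loglik <- function(S, W, eps = 1e-10, lag = 0) {
  n <- nrow(S); T <- ncol(S)
  ll <- 0
  for (t in seq_len(T)) {
    if (t - lag < 1) next
    for (i in seq_len(n)) {
      I <- 0
      for (j in seq_len(n)) {
        if (j != i) I <- I + S[j, t - lag] * W[i, j]
      }
      p <- min(max(I / n, eps), 1 - eps)
      ll <- ll + if (S[i, t] == 1) log(p) else log(1 - p)
    }
  }
  ll
}

## spatial-GLM log-likelihood, triple loop with lag-1 logistic link
loop_glm_loglik <- function(S, W, r0, alpha) {
  n <- nrow(S); T <- ncol(S)
  ll <- 0
  for (t in 2:T) {
    for (i in seq_len(n)) {
      h <- r0
      for (j in seq_len(n)) {
        if (j != i) h <- h + alpha * S[j, t - 1] * W[i, j]
      }
      p <- 1 / (1 + exp(-h))
      ll <- ll + if (S[i, t] == 1) log(p) else log(1 - p)
    }
  }
  ll
}

## transfer entropy by explicit enumeration of the 8 binary states
## (k = l = 1, delay 1): TE(X -> Y) in bits
loop_te <- function(x, y) {
  T <- length(x)
  ## one-step histories with delay 1: predict y at t = 2..T from
  ## y(t-1) and x(t-1)
  yn <- y[2:T]; yh <- y[1:(T - 1)]; xh <- x[1:(T - 1)]
  n <- length(yn)
  te <- 0
  for (a in 0:1) for (b in 0:1) for (c in 0:1) {
    n_abc <- sum(yn == a & yh == b & xh == c)
    if (n_abc == 0) next
    n_bc <- sum(yh == b & xh == c)
    n_ab <- sum(yn == a & yh == b)
    n_b <- sum(yh == b)
    te <- te + n_abc / n * log2((n_abc / n_bc) / (n_ab / n_b))
  }
  te
}

## two-pass textbook Pearson correlation
loop_pearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

## single Izhikevich neuron, literal transcription of the update used as an
## independent reference: two half-steps for v, one for u, reset at 30 mV
loop_izhikevich_neuron <- function(I, dt, steps,
                                   a = 0.02, b = 0.2, c = -65, d = 8) {
  v <- c; u <- b * v
  spikes <- 0
  for (s in seq_len(steps)) {
    v <- v + dt / 2 * (0.04 * v^2 + 5 * v + 140 - u + I)
    v <- v + dt / 2 * (0.04 * v^2 + 5 * v + 140 - u + I)
    u <- u + dt * a * (b * v - u)
    if (v >= 30) {
      v <- c
      u <- u + d
      spikes <- spikes + 1
    }
  }
  spikes
}

## small deterministic raster used by several oracle comparisons
toy_raster_matrix <- function() {
  rbind(c(0, 1, 0, 1),
        c(1, 0, 1, 0),
        c(0, 1, 1, 0))
}

toy_geometry <- function() {
  pairwise_distances(rbind(c(0, 0), c(0.1, 0), c(0, 0.25)))
}
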