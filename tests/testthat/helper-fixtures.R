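# Shared fixtures and independent oracles.

# small three-item model exercising distinct parameter regimes
toy_model3 <- function() {
  ggum_model(list(
    ggum_item("a", alpha = 1.2, delta = -0.9, tau = -1.1),
    ggum_item("b", alpha = 0.8, delta = 0.2, tau = -0.6),
    ggum_item("c", alpha = 1.5, delta = 1.1, tau = -1.4)))
}

# binary GGUM consumption probability written directly from the response
# function with H = 1, M = 3 (independent of the package's implementation)
oracle_p1 <- function(alpha, delta, tau, theta) {
  u <- theta - delta
  num <- exp(alpha * (u - tau)) + exp(alpha * (2 * u - tau))
  den <- 1 + exp(3 * alpha * u) + num
  num / den
}

# dense-grid marginal likelihood oracle: direct product-and-sum integration
# on a 10^4-node trapezoid grid with renormalized normal weights
oracle_lml <- function(model, responses, n_nodes = 1e4, bounds = c(-4, 4)) {
  th <- seq(bounds[1], bounds[2], length.out = n_nodes)
  w <- dnorm(th); w[c(1, n_nodes)] <- w[c(1, n_nodes)] / 2; w <- w / sum(w)
  P <- sapply(model$items, function(it)
    oracle_p1(it$alpha, it$delta, it$tau, th))
  total <- 0
  for (j in seq_len(nrow(responses))) {
    lik <- rep(1, n_nodes)
    for (i in seq_len(ncol(responses)))
      lik <- lik * (if (responses[j, i] == 1) P[, i] else 1 - P[, i])
    total <- total + log(sum(lik * w))
  }
  total
}

# dense-grid posterior mean / sd oracle for one response pattern
oracle_eap <- function(model, pattern, n_nodes = 1e4, bounds = c(-4, 4)) {
  th <- seq(bounds[1], bounds[2], length.out = n_nodes)
  w <- dnorm(th); w[c(1, n_nodes)] <- w[c(1, n_nodes)] / 2; w <- w / sum(w)
  lik <- rep(1, n_nodes)
  for (i in seq_along(pattern)) {
    it <- model$items[[i]]
    p <- oracle_p1(it$alpha, it$delta, it$tau, th)
    lik <- lik * (if (pattern[i] == 1) p else 1 - p)
  }
  post <- lik * w / sum(lik * w)
  mu <- sum(post * th)
  list(mean = mu, sd = sqrt(sum(post * th^2) - mu^2))
}

# all 2^k binary response patterns as a matrix
all_patterns <- function(k) {
  as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
}

random_items <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    ggum_item(sprintf("r%02d", i), alpha = runif(1, 0.3, 2.5),
              delta = runif(1, -2, 2), tau = runif(1, -2, 0.5)))
}
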