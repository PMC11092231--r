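test_that("category probabilities are normalized and bounded for arbitrary items", {
  items <- c(random_items(8, seed = 1),
             list(ggum_item("poly", 1.3, -0.4, tau = c(-1.5, -0.8, 0.3))))
  th <- seq(-6, 6, by = 0.25)
  for (it in items) {
    curve <- ggum_icc(it, th)
    expect_true(all(curve$probabilities >= 0 & curve$probabilities <= 1))
    expect_lt(max(abs(rowSums(curve$probabilities) - 1)), 1e-10)
  }
})

test_that("the peak probability reduces to the logistic closed form", {
  for (it in random_items(10, seed = 2)) {
    closed <- exp(-it$alpha * it$tau) / (1 + exp(-it$alpha * it$tau))
    expect_equal(ggum_probability(it, it$delta, 1L), closed, tolerance = 1e-12)
    expect_equal(oracle_p1(it$alpha, it$delta, it$tau, it$delta), closed,
                 tolerance = 1e-12)
  }
})

test_that("the consumption curve is symmetric about the item location", {
  u <- seq(0.05, 4, by = 0.05)
  for (it in random_items(6, seed = 3)) {
    expect_lt(max(abs(ggum_probability(it, it$delta + u, 1L) -
                        ggum_probability(it, it$delta - u, 1L))), 1e-10)
  }
})

test_that("the curve peaks at delta, and crossings exist iff tau is negative", {
  th <- seq(-5, 5, by = 1e-3)
  for (it in random_items(12, seed = 4)) {
    p1 <- ggum_probability(it, th, 1L)
    expect_lt(abs(th[which.max(p1)] - it$delta), 2e-3)
    peak <- ggum_probability(it, it$delta, 1L)
    expect_identical(peak > 0.5, it$tau < 0)
  }
  # item whose consumption curve never reaches one half
  flat <- ggum_item("i04like", 1.11, -0.47, tau = 0.2)
  expect_true(all(ggum_probability(flat, th, 1L) < 0.5))
})

test_that("probability inputs are validated", {
  it <- ggum_item("a", 1, 0, -1)
  expect_error(ggum_probability(it, 0, 2L), "category")
  expect_error(ggum_probability(it, NaN, 1L), "finite")
  expect_error(ggum_icc(it, numeric(0)), "non-empty")
  expect_error(ggum_icc(it, c(1, 0)), "sorted")
  expect_error(ggum_item("bad", -1, 0, -1), "alpha")
})

test_that("item information matches a central-difference derivative oracle", {
  th <- seq(-3, 3, by = 0.5)
  h <- 1e-6
  for (it in random_items(6, seed = 5)) {
    info <- item_information(it, th)
    expect_true(all(info >= 0))
    num <- sapply(th, function(t0) {
      dp1 <- (ggum_probability(it, t0 + h, 1L) -
                ggum_probability(it, t0 - h, 1L)) / (2 * h)
      p1 <- ggum_probability(it, t0, 1L)
      dp1^2 / p1 + dp1^2 / (1 - p1)
    })
    expect_lt(max(abs(info - num)), 1e-5)
  }
  # saturation far from the item location
  expect_lt(max(item_information(toy_model3()$items[[1]], c(-30, 30))), 1e-8)
  # the binary consumption curve is flat at its peak, so a binary item
  # carries no information exactly at its own location...
  lo <- ggum_item("lo", 0.8, 0, -1)
  hi <- ggum_item("hi", 1.6, 0, -1)
  expect_identical(item_information(lo, 0), 0)
  # ...and sharper discrimination concentrates information on the flanks
  expect_gt(item_information(hi, 0.9), item_information(lo, 0.9))
})

test_that("test information is additive and SE is its inverse square root", {
  m <- toy_model3()
  th <- seq(-4, 4, by = 0.1)
  tic <- test_information(m, th)
  expect_equal(tic$information,
               Reduce(`+`, lapply(m$items, item_information, theta = th)))
  expect_equal(tic$se[tic$information > 0],
               1 / sqrt(tic$information[tic$information > 0]))
  one <- test_information(ggum_model(m$items[1]), th)
  expect_equal(one$information, item_information(m$items[[1]], th))
  doubled <- ggum_model(c(m$items, lapply(m$items, function(it) {
    it$item_id <- paste0(it$item_id, "_copy"); it
  })))
  expect_equal(test_information(doubled, th)$information,
               2 * tic$information, tolerance = 1e-12)
  # probabilities saturate far out, so information underflows to zero and
  # the standard error is reported as the infinity sentinel
  far <- test_information(m, c(-2000, 2000))
  expect_identical(far$information, c(0, 0))
  expect_identical(far$se, c(Inf, Inf))
})

test_that("the reference scale is most informative inside [-2, 2]", {
  th <- seq(-4, 4, by = 0.01)
  tic <- test_information(mesa_reference_model(), th)
  argmax <- th[which.max(tic$information)]
  expect_gt(argmax, -2)
  expect_lt(argmax, 2)
})

test_that("marginal likelihood matches dense-grid integration on all patterns", {
  m <- toy_model3()
  pats <- all_patterns(3)
  for (j in seq_len(nrow(pats))) {
    got <- log_marginal_likelihood(m, pats[j, , drop = FALSE])
    expect_lt(abs(got - oracle_lml(m, pats[j, , drop = FALSE])), 1e-6)
  }
  # jointly, and invariant to respondent order
  set.seed(10)
  X <- pats[sample.int(8, 5, replace = TRUE), ]
  ll <- log_marginal_likelihood(m, X)
  expect_lt(abs(ll - oracle_lml(m, X)), 1e-6)
  expect_equal(log_marginal_likelihood(m, X[5:1, ]), ll)
})

test_that("single-item pattern likelihoods marginalize to one", {
  it <- ggum_item("solo", 1.1, -0.3, -0.9)
  m <- ggum_model(list(it))
  p <- exp(log_marginal_likelihood(m, matrix(0, 1, 1))) +
    exp(log_marginal_likelihood(m, matrix(1, 1, 1)))
  expect_equal(p, 1, tolerance = 1e-12)
})

test_that("quadrature refinement leaves the likelihood unchanged below 1e-6", {
  m <- toy_model3()
  set.seed(11)
  X <- all_patterns(3)[sample.int(8, 5, replace = TRUE), ]
  ll61 <- log_marginal_likelihood(m, X, ggum_quadrature(61))
  ll121 <- log_marginal_likelihood(m, X, ggum_quadrature(121))
  expect_lt(abs(ll61 - ll121), 1e-6)
})

test_that("likelihood rejects mismatched response matrices", {
  m <- toy_model3()
  expect_error(log_marginal_likelihood(m, matrix(0, 2, 2)), "columns")
  expect_error(log_marginal_likelihood(m, matrix(2, 1, 3)), "integers in 0")
})

test_that("model JSON serialization round-trips at full precision", {
  m <- ggum_model(random_items(5, seed = 6),
                  level_cutoffs = c(lower = 95, upper = 101))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  for (i in seq_along(m$items)) {
    expect_identical(signif(m2$items[[i]]$alpha, 15), signif(m$items[[i]]$alpha, 15))
    expect_identical(signif(m2$items[[i]]$delta, 15), signif(m$items[[i]]$delta, 15))
    expect_identical(signif(m2$items[[i]]$tau, 15), signif(m$items[[i]]$tau, 15))
  }
  expect_identical(m2$transformation, m$transformation)
  expect_identical(m2$level_cutoffs, m$level_cutoffs)
})

test_that("model construction enforces its invariants", {
  its <- random_items(3, seed = 7)
  expect_error(ggum_model(c(its, its[1])), "unique")
  expect_error(ggum_model(its, trait_sd = 0), "trait_sd")
  expect_error(ggum_model(its, level_cutoffs = c(lower = 101, upper = 95)),
               "lower < upper")
})
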