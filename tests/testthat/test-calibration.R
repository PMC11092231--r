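# five well-conditioned items: every 0.5-crossing lies inside +/-2, where a
# N(0,1) population actually observes it (edge items leave location and
# threshold jointly underdetermined)
calib_model5 <- function() {
  ggum_model(list(
    ggum_item("a", 1.6, -1.0, -0.8), ggum_item("b", 1.4, -0.5, -0.9),
    ggum_item("c", 1.5, 0.0, -0.8), ggum_item("d", 1.4, 0.5, -0.9),
    ggum_item("e", 1.6, 1.0, -0.8)))
}

test_that("EAP scores match dense-grid posterior integration on all patterns", {
  m <- toy_model3()
  pats <- all_patterns(3)
  rownames(pats) <- sprintf("p%d", seq_len(nrow(pats)))
  sc <- eap_scores(m, pats)
  for (j in seq_len(nrow(pats))) {
    orc <- oracle_eap(m, pats[j, ])
    expect_lt(abs(sc$theta_eap[j] - orc$mean), 1e-5)
    expect_lt(abs(sc$posterior_sd[j] - orc$sd), 1e-5)
  }
  expect_equal(sc$score, to_reporting_scale(sc$theta_eap))
  expect_equal(sc$level, assign_level(sc$score))
})

test_that("identical response patterns receive identical scores", {
  m <- toy_model3()
  X <- rbind(c(1, 0, 1), c(0, 1, 0), c(1, 0, 1), c(1, 0, 1))
  sc <- eap_scores(m, X)
  expect_identical(sc$theta_eap[1], sc$theta_eap[3])
  expect_identical(sc$theta_eap[1], sc$theta_eap[4])
  expect_false(sc$theta_eap[1] == sc$theta_eap[2])
})

test_that("EAP shrinks toward the prior and respects its sign logic", {
  # all items located on the positive side: a non-consumer of everything
  # most plausibly sits on the negative side
  m <- ggum_model(list(ggum_item("a", 1.2, 0.5, -1), ggum_item("b", 1.0, 1.0, -1),
                       ggum_item("c", 1.4, 1.5, -1)))
  sc0 <- eap_scores(m, matrix(0, 1, 3))
  expect_lt(sc0$theta_eap, 0)
  expect_lt(abs(sc0$theta_eap - oracle_eap(m, c(0, 0, 0))$mean), 1e-5)
  # posterior means never escape the quadrature support
  sc <- eap_scores(m, all_patterns(3))
  expect_true(all(abs(sc$theta_eap) <= 4))
})

test_that("the EM fit recovers generating parameters and tightens with N", {
  m <- calib_model5()
  gen <- t(vapply(m$items, function(it) c(it$alpha, it$delta, it$tau),
                  numeric(3)))
  cfg <- list(orientation = list(item = "a", sign = -1))
  sim_small <- simulate_responses(
    simulation_config(n_respondents = 2000, model = m, seed = 101))
  sim_big <- simulate_responses(
    simulation_config(n_respondents = 50000, model = m, seed = 101))
  fit_small <- fit_ggum_mml(sim_small$responses, cfg)
  fit_big <- fit_ggum_mml(sim_big$responses, cfg)
  err_small <- abs(as.matrix(fit_small$estimates[, c("alpha", "delta", "tau")]) - gen)
  err_big <- abs(as.matrix(fit_big$estimates[, c("alpha", "delta", "tau")]) - gen)
  expect_lt(median(err_big), median(err_small))
  expect_lt(median(err_big), 0.05)
  expect_lt(max(err_big[, "delta"]), 0.1)
  expect_true(fit_big$converged)
})

test_that("the EM marginal likelihood never decreases", {
  m <- calib_model5()
  sim <- simulate_responses(
    simulation_config(n_respondents = 1000, model = m, seed = 7))
  fit <- fit_ggum_mml(sim$responses)
  expect_true(all(diff(fit$ll_trace) > -1e-8))
})

test_that("estimates are invariant to respondent order", {
  m <- calib_model5()
  sim <- simulate_responses(
    simulation_config(n_respondents = 800, model = m, seed = 8))
  fit1 <- fit_ggum_mml(sim$responses)
  perm <- rev(seq_len(nrow(sim$responses)))
  fit2 <- fit_ggum_mml(sim$responses[perm, ])
  expect_equal(fit1$estimates$alpha, fit2$estimates$alpha, tolerance = 1e-8)
  expect_equal(fit1$estimates$delta, fit2$estimates$delta, tolerance = 1e-8)
})

test_that("degenerate and invalid inputs are rejected with named items", {
  X <- cbind(i1 = c(0, 1, 0, 1), i2 = c(1, 1, 1, 1))
  expect_error(suppressWarnings(fit_ggum_mml(X)), "i2")
  expect_error(fit_ggum_mml(matrix(1, 5, 1)), "two items")
  expect_error(suppressWarnings(fit_ggum_mml(matrix(c(0, 1, 2, 1), 2, 2))),
               "binary")
})

test_that("the orientation convention pins the reflection-invariant solution", {
  m <- calib_model5()
  sim <- simulate_responses(
    simulation_config(n_respondents = 1500, model = m, seed = 9))
  fit_neg <- fit_ggum_mml(sim$responses,
                          list(orientation = list(item = "a", sign = -1)))
  fit_pos <- fit_ggum_mml(sim$responses,
                          list(orientation = list(item = "a", sign = 1)))
  expect_lt(fit_neg$estimates$delta[1], 0)
  expect_gt(fit_pos$estimates$delta[1], 0)
  # mirrored locations, identical discriminations and thresholds, same fit
  expect_equal(fit_neg$estimates$delta, -fit_pos$estimates$delta)
  expect_equal(fit_neg$estimates$alpha, fit_pos$estimates$alpha)
  expect_equal(fit_neg$log_likelihood, fit_pos$log_likelihood, tolerance = 1e-8)
})

test_that("bootstrap SEs are seed-deterministic and warn when few replicates", {
  m <- calib_model5()
  sim <- simulate_responses(
    simulation_config(n_respondents = 600, model = m, seed = 12))
  cfg <- list(tol_par = 1e-3, tol_rel_ll = 1e-7)
  expect_warning(b1 <- bootstrap_se(sim$responses, cfg, n_boot = 2, seed = 3),
                 "n_boot")
  b2 <- suppressWarnings(bootstrap_se(sim$responses, cfg, n_boot = 2, seed = 3))
  expect_identical(b1$se, b2$se)
})

test_that("bootstrap SEs agree with observed-information SEs and shrink with N", {
  m <- calib_model5()
  bcfg <- list(orientation = list(item = "a", sign = -1),
               tol_par = 1e-3, tol_rel_ll = 1e-7)
  sim <- simulate_responses(
    simulation_config(n_respondents = 1200, model = m, seed = 5))
  fit <- fit_ggum_mml(sim$responses,
                      list(orientation = list(item = "a", sign = -1),
                           se = "hessian"))
  boot <- suppressWarnings(bootstrap_se(sim$responses, bcfg, n_boot = 60,
                                        seed = 6))
  ratio <- boot$se$delta_se / fit$estimates$delta_se
  expect_true(all(abs(ratio - 1) <= 0.3))
  # quadrupling N should roughly halve the SEs
  sim4 <- simulate_responses(
    simulation_config(n_respondents = 4800, model = m, seed = 5))
  boot4 <- suppressWarnings(bootstrap_se(sim4$responses, bcfg, n_boot = 40,
                                         seed = 6))
  shrink <- median(boot$se$delta_se / boot4$se$delta_se)
  expect_gt(shrink, 1.4)
  expect_lt(shrink, 2.9)
})
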