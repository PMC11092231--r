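# MML-EM estimation for the dichotomous unfolding model.
#
# The latent trait is integrated out on a fixed quadrature grid against a
# N(0,1) weighting (the identification constraint: the trait metric is the
# respondent distribution). The E-step computes posterior node weights per
# unique response pattern; the M-step improves each item's expected
# complete-data log-likelihood with a bounded quasi-Newton step (a
# generalized EM: any improvement keeps the marginal likelihood monotone).

.default_calib_config <- function() {
  list(quad_nodes = 61L, quad_bounds = c(-4, 4),
       max_iter = 500L, tol_rel_ll = 1e-6, tol_par = 1e-4,
       mstep_maxit = 15L,
       alpha_bounds = c(0.05, 5), delta_bounds = c(-4, 4),
       tau_bounds = c(-4, 2),
       start = NULL, orientation = NULL, se = "none", verbose = FALSE)
}

.calib_config <- function(config = list()) {
  cfg <- .default_calib_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown calibration option(s): ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  cfg
}

# P(consumption) for a bank of binary items at the quadrature nodes.
# parmat: I x 3 (alpha, delta, tau). Returns Q x I.
.prob1_bank <- function(parmat, nodes) {
  Q <- length(nodes); I <- nrow(parmat)
  A <- matrix(parmat[, 1L], Q, I, byrow = TRUE)
  U <- outer(nodes, parmat[, 2L], `-`)
  Tm <- matrix(parmat[, 3L], Q, I, byrow = TRUE)
  e0a <- matrix(0, Q, I)
  e0b <- 3 * A * U
  e1a <- A * (U - Tm)
  e1b <- A * (2 * U - Tm)
  m <- pmax(e0a, e0b, e1a, e1b)
  n1 <- exp(e1a - m) + exp(e1b - m)
  n0 <- exp(e0a - m) + exp(e0b - m)
  n1 / (n0 + n1)
}

.collapse_patterns <- function(responses) {
  key <- apply(responses, 1L, paste, collapse = "")
  first <- !duplicated(key)
  Xp <- responses[first, , drop = FALSE]
  idx <- match(key, key[first])
  list(Xp = Xp, counts = as.numeric(tabulate(idx, nbins = sum(first))),
       index = idx)
}

# Marginal log-likelihood plus posterior node weights for pattern data.
.estep <- function(parmat, Xp, counts, nodes, logw) {
  P1 <- .prob1_bank(parmat, nodes)
  logP1 <- log(pmax(P1, .Machine$double.xmin))
  logP0 <- log(pmax(1 - P1, .Machine$double.xmin))
  L <- Xp %*% t(logP1) + (1 - Xp) %*% t(logP0)
  A <- sweep(L, 2L, logw, `+`)
  m <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  E <- exp(A - m)
  rs <- rowSums(E)
  list(ll = sum(counts * (m + log(rs))), post = E * (counts / rs))
}

.ll_only <- function(parmat, Xp, counts, nodes, logw) {
  .estep(parmat, Xp, counts, nodes, logw)$ll
}

# One item's negative expected complete-data log-likelihood.
.item_objective <- function(par, r1, r0, nodes) {
  p1 <- .prob1_bank(matrix(par, 1L), nodes)[, 1L]
  -sum(r1 * log(pmax(p1, 1e-300)) + r0 * log(pmax(1 - p1, 1e-300)))
}

.mstep_item <- function(par, r1, r0, nodes, cfg) {
  lower <- c(cfg$alpha_bounds[1], cfg$delta_bounds[1], cfg$tau_bounds[1])
  upper <- c(cfg$alpha_bounds[2], cfg$delta_bounds[2], cfg$tau_bounds[2])
  f0 <- .item_objective(par, r1, r0, nodes)
  opt <- try(stats::optim(par, .item_objective, r1 = r1, r0 = r0,
                          nodes = nodes, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = cfg$mstep_maxit)),
             silent = TRUE)
  if (inherits(opt, "try-error") || opt$value > f0) par else opt$par
}

.start_parmat <- function(responses, cfg) {
  I <- ncol(responses)
  if (!is.null(cfg$start)) {
    parmat <- cfg$start
    stopifnot(is.matrix(parmat), nrow(parmat) == I, ncol(parmat) == 3L)
    return(parmat)
  }
  # location heuristic: endorsers of an item sit near its location, so the
  # mean principal-component score of its endorsers ranks the deltas.
  Xs <- scale(responses)
  v <- eigen(stats::cor(responses), symmetric = TRUE)$vectors[, 1L]
  s <- as.numeric(Xs %*% v)
  d <- vapply(seq_len(I), function(i) mean(s[responses[, i] == 1]), numeric(1))
  if (stats::sd(d) > 0) d <- 0.8 * (d - mean(d)) / stats::sd(d)
  d <- pmin(pmax(d, -2), 2)
  cbind(alpha = rep(1, I), delta = d, tau = rep(-1, I))
}

.check_binary_items <- function(responses) {
  cm <- colMeans(responses)
  if (any(cm == 0 | cm == 1))
    stop("degenerate item(s) with a single observed category: ",
         paste(colnames(responses)[cm == 0 | cm == 1], collapse = ", "))
}

#' Fit the binary GGUM by marginal maximum likelihood
#'
#' EM estimation of discrimination, location and threshold for every item of
#' a binary response matrix, with the latent trait fixed at N(0,1) for
#' identification. The marginal log-likelihood is non-decreasing across
#' iterations; convergence requires both a relative log-likelihood change
#' below `tol_rel_ll` and a maximum parameter change below `tol_par`.
#'
#' The marginal likelihood is exactly invariant under jointly reflecting all
#' item locations about zero (the mirrored scale fits the data identically),
#' so the fitted orientation is arbitrary. Pass
#' `orientation = list(item =, sign =)` to resolve it by convention, e.g.
#' anchor the MPF-at-breakfast item to the negative (healthy) side.
#'
#' @param responses binary matrix, respondents x items, with column names.
#' @param config named list overriding the defaults: `quad_nodes` (61),
#'   `quad_bounds` (c(-4, 4)), `max_iter` (500), `tol_rel_ll` (1e-6),
#'   `tol_par` (1e-4), `mstep_maxit`, parameter boxes `alpha_bounds`
#'   ((0.05, 5]), `delta_bounds` ([-4, 4]), `tau_bounds` ([-4, 2]), `start`
#'   (I x 3 matrix), `orientation`, `se` ("none" or "hessian"), `verbose`.
#' @return A `ggum_fit`: list with `model` (a [ggum_model()]), `estimates`
#'   (data frame of parameters and, if requested, SEs), `log_likelihood`,
#'   `ll_trace`, `n_iterations`, `converged`, `bound_items`, `settings`.
#' @export
fit_ggum_mml <- function(responses, config = list()) {
  cfg <- .calib_config(config)
  responses <- as.matrix(responses)
  storage.mode(responses) <- "double"
  if (is.null(colnames(responses)))
    colnames(responses) <- sprintf("item%02d", seq_len(ncol(responses)))
  if (ncol(responses) < 2L) stop("at least two items are required")
  if (!all(responses %in% c(0, 1))) stop("responses must be binary 0/1")
  .check_binary_items(responses)
  if (nrow(responses) < 250L)
    warning("fewer than 250 respondents; item parameter estimates may be unstable")

  quad <- ggum_quadrature(cfg$quad_nodes, cfg$quad_bounds)
  nodes <- quad$nodes; logw <- log(quad$weights)
  pat <- .collapse_patterns(responses)
  parmat <- .start_parmat(responses, cfg)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    es <- .estep(parmat, pat$Xp, pat$counts, nodes, logw)
    if (es$ll < ll_old - 1e-8)
      warning(sprintf("EM log-likelihood decreased at iteration %d (%.3g)",
                      iter, es$ll - ll_old))
    ll_trace <- c(ll_trace, es$ll)
    Nq <- colSums(es$post)
    r1 <- t(pat$Xp) %*% es$post
    parmat_new <- parmat
    for (i in seq_len(nrow(parmat)))
      parmat_new[i, ] <- .mstep_item(parmat[i, ], r1[i, ], Nq - r1[i, ],
                                     nodes, cfg)
    dpar <- max(abs(parmat_new - parmat))
    dll <- abs(es$ll - ll_old) / (abs(es$ll) + .Machine$double.eps)
    if (cfg$verbose)
      message(sprintf("iter %3d  ll %.6f  dpar %.2e", iter, es$ll, dpar))
    parmat <- parmat_new
    if (iter > 1L && dll < cfg$tol_rel_ll && dpar < cfg$tol_par) {
      converged <- TRUE
      break
    }
    ll_old <- es$ll
  }
  if (!converged)
    warning("EM did not converge within ", cfg$max_iter, " iterations")

  if (!is.null(cfg$orientation)) {
    o <- cfg$orientation
    i <- match(o$item, colnames(responses))
    if (is.na(i)) stop("orientation item not found: ", o$item)
    if (sign(parmat[i, 2L]) != 0 && sign(parmat[i, 2L]) != sign(o$sign))
      parmat[, 2L] <- -parmat[, 2L]
  }
  ll_final <- .ll_only(parmat, pat$Xp, pat$counts, nodes, logw)

  at_bound <- parmat[, 1L] <= cfg$alpha_bounds[1] + 1e-8 |
    parmat[, 1L] >= cfg$alpha_bounds[2] - 1e-8 |
    parmat[, 2L] <= cfg$delta_bounds[1] + 1e-8 |
    parmat[, 2L] >= cfg$delta_bounds[2] - 1e-8 |
    parmat[, 3L] <= cfg$tau_bounds[1] + 1e-8 |
    parmat[, 3L] >= cfg$tau_bounds[2] - 1e-8

  est <- data.frame(item = colnames(responses),
                    alpha = parmat[, 1L], delta = parmat[, 2L],
                    tau = parmat[, 3L], stringsAsFactors = FALSE)
  if (identical(cfg$se, "hessian")) {
    ses <- .hessian_se(parmat, pat, nodes, logw)
    est$alpha_se <- ses[, 1L]; est$delta_se <- ses[, 2L]
    est$tau_se <- ses[, 3L]
  }
  items <- lapply(seq_len(nrow(est)), function(i)
    ggum_item(est$item[i], est$alpha[i], est$delta[i], est$tau[i]))
  structure(
    list(model = ggum_model(items), estimates = est,
         log_likelihood = ll_final, ll_trace = ll_trace,
         n_iterations = iter, converged = converged,
         bound_items = colnames(responses)[at_bound], settings = cfg),
    class = "ggum_fit")
}

#' @export
print.ggum_fit <- function(x, ...) {
  cat(sprintf("GGUM MML fit: %d items, logLik %.2f, %d EM iterations (%s)\n",
              nrow(x$estimates), x$log_likelihood, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(x$estimates, digits = 3)
  invisible(x)
}

# Observed-information standard errors: numerical Hessian of the marginal
# log-likelihood over the stacked (alpha, delta, tau) vector.
.hessian_se <- function(parmat, pat, nodes, logw, h = 1e-4) {
  I <- nrow(parmat)
  p0 <- as.numeric(parmat)
  f <- function(p) .ll_only(matrix(p, I), pat$Xp, pat$counts, nodes, logw)
  np <- length(p0)
  H <- matrix(NA_real_, np, np)
  for (a in seq_len(np)) {
    for (b in a:np) {
      pa <- p0; pa[a] <- pa[a] + h; pa[b] <- pa[b] + h; fpp <- f(pa)
      pa <- p0; pa[a] <- pa[a] + h; pa[b] <- pa[b] - h; fpm <- f(pa)
      pa <- p0; pa[a] <- pa[a] - h; pa[b] <- pa[b] + h; fmp <- f(pa)
      pa <- p0; pa[a] <- pa[a] - h; pa[b] <- pa[b] - h; fmm <- f(pa)
      H[a, b] <- H[b, a] <- (fpp - fpm - fmp + fmm) / (4 * h * h)
    }
  }
  V <- try(solve(-H), silent = TRUE)
  if (inherits(V, "try-error") || any(diag(V) <= 0)) {
    warning("observed information not positive definite; SEs set to NA")
    return(matrix(NA_real_, I, 3L))
  }
  matrix(sqrt(diag(V)), I)
}

#' Table of calibrated item parameters
#'
#' @param fit a `ggum_fit` from [fit_ggum_mml()].
#' @return Data frame with columns item, alpha, delta, tau and SEs when
#'   available.
#' @export
calibration_table <- function(fit) {
  stopifnot(inherits(fit, "ggum_fit"))
  fit$estimates
}

#' Expected a posteriori trait scores
#'
#' Posterior mean and SD of the latent trait for each respondent given the
#' calibrated model, computed on the quadrature grid, then transformed to the
#' reporting scale and classified into meal-quality levels. Identical
#' response patterns receive identical scores.
#'
#' @param model a [ggum_model()].
#' @param responses binary matrix whose columns match the model items.
#' @param quad quadrature grid (default matches the calibration default).
#' @return Data frame: `child_id`, `theta_eap`, `posterior_sd`, `score`
#'   (reporting scale), `level`.
#' @export
eap_scores <- function(model, responses, quad = ggum_quadrature()) {
  responses <- .check_responses(model, responses)
  ids <- rownames(responses)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(responses)))
  pat <- .collapse_patterns(responses)
  tabs <- .log_prob_tables(model, quad$nodes)
  L <- .pattern_loglik(model, pat$Xp, tabs)
  A <- sweep(L, 2L, log(quad$weights), `+`)
  m <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  W <- exp(A - m)
  W <- W / rowSums(W)
  mu <- as.numeric(W %*% quad$nodes)
  m2 <- as.numeric(W %*% quad$nodes^2)
  psd <- sqrt(pmax(m2 - mu^2, 0))
  score <- to_reporting_scale(mu, model$transformation)
  data.frame(child_id = ids,
             theta_eap = mu[pat$index],
             posterior_sd = psd[pat$index],
             score = score[pat$index],
             level = assign_level(score, model$level_cutoffs)[pat$index],
             stringsAsFactors = FALSE)
}

#' Bootstrap standard errors for item parameters
#'
#' Nonparametric respondent resampling: the model is refit on each bootstrap
#' sample (warm-started at the full-data estimates) and the SE of each
#' parameter is the SD of its bootstrap estimates. Each refit is reflected,
#' if needed, to match the orientation of the full-data fit before
#' aggregation, since the two mirror-image solutions are observationally
#' equivalent. Non-convergent refits are dropped and counted.
#'
#' @param responses binary response matrix.
#' @param config calibration config passed to [fit_ggum_mml()].
#' @param n_boot number of bootstrap replicates (values below 50 trigger a
#'   warning; SEs are then indicative only).
#' @param seed integer seed; the replicate stream is derived from it.
#' @return List with `se` (data frame item, alpha_se, delta_se, tau_se),
#'   `n_failed`, and `estimates` (array of replicate estimates).
#' @export
bootstrap_se <- function(responses, config = list(), n_boot = 100L, seed) {
  stopifnot(!missing(seed))
  if (n_boot < 50L)
    warning("n_boot < 50; bootstrap SEs will be unreliable")
  responses <- as.matrix(responses)
  base <- fit_ggum_mml(responses, config)
  I <- ncol(responses)
  out <- array(NA_real_, c(n_boot, I, 3L),
               dimnames = list(NULL, base$estimates$item,
                               c("alpha", "delta", "tau")))
  failed <- 0L
  cfg <- config
  cfg$start <- as.matrix(base$estimates[, c("alpha", "delta", "tau")])
  for (b in seq_len(n_boot)) {
    idx <- .with_seed(seed + b, sample.int(nrow(responses), replace = TRUE))
    fit_b <- tryCatch(
      suppressWarnings(fit_ggum_mml(responses[idx, , drop = FALSE], cfg)),
      error = function(e) NULL)
    if (is.null(fit_b) || !fit_b$converged) { failed <- failed + 1L; next }
    pb <- as.matrix(fit_b$estimates[, c("alpha", "delta", "tau")])
    if (sum(pb[, 2L] * cfg$start[, 2L]) < 0) pb[, 2L] <- -pb[, 2L]
    out[b, , ] <- pb
  }
  ses <- apply(out, c(2L, 3L), stats::sd, na.rm = TRUE)
  list(se = data.frame(item = base$estimates$item,
                       alpha_se = ses[, "alpha"], delta_se = ses[, "delta"],
                       tau_se = ses[, "tau"], stringsAsFactors = FALSE),
       n_failed = failed, estimates = out)
}

# Evaluate an expression with a temporary RNG state seeded at `seed`,
# restoring the caller's state afterwards.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
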