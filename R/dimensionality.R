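# Unidimensionality diagnostics for the binary consumption items:
# tetrachoric correlations, minimum-residual factoring with optional oblimin
# (quartimin) rotation, and the loading/communality/discrimination retention
# filter that reduces the 18 candidate items to the final scale.

# Standard bivariate normal CDF P(X < h, Y < k; rho), reduced to a single
# integral over the conditional normal CDF.
.pbvnorm <- function(h, k, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(h) * stats::pnorm(k))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) stats::dnorm(x) * stats::pnorm((k - rho * x) / s),
                   -Inf, h, rel.tol = 1e-10)$value
}

# Tetrachoric correlation of one 2x2 table via the standard latent bivariate
# normal model: thresholds from the margins, rho solved so the model joint
# (1,1) probability matches the observed one. A 0.5 continuity correction is
# applied to empty cells.
.tetrachoric_pair <- function(x, y) {
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  if (min(n11, n10, n01, n00) == 0) {
    n11 <- n11 + 0.5; n10 <- n10 + 0.5; n01 <- n01 + 0.5; n00 <- n00 + 0.5
  }
  n <- n11 + n10 + n01 + n00
  p1x <- (n11 + n10) / n; p1y <- (n11 + n01) / n
  h <- stats::qnorm(p1x); k <- stats::qnorm(p1y)
  target <- n11 / n
  # with thresholds at qnorm(p1.), the model joint (1,1) probability is
  # P(X < h, Y < k; rho) by symmetry of the latent normal
  g <- function(r) .pbvnorm(h, k, r) - target
  if (abs(g(0)) < 1e-12) return(0)
  lo <- -0.9999; hi <- 0.9999
  if (g(lo) > 0) return(-1)
  if (g(hi) < 0) return(1)
  stats::uniroot(g, c(lo, hi), tol = 1e-9)$root
}

#' Tetrachoric correlation matrix of binary items
#'
#' Pairwise tetrachoric correlations under the latent bivariate-normal
#' model, used as the input to item factor analysis. If the assembled matrix
#' is not positive semidefinite it is repaired by flooring its eigenvalues
#' at 1e-6 and rescaling back to unit diagonal.
#'
#' @param responses binary matrix, respondents x items; every item must show
#'   both categories.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
tetrachoric_matrix <- function(responses) {
  responses <- as.matrix(responses)
  cm <- colMeans(responses)
  if (any(cm == 0 | cm == 1))
    stop("degenerate item(s) with a single observed category: ",
         paste(colnames(responses)[cm == 0 | cm == 1], collapse = ", "))
  I <- ncol(responses)
  R <- diag(1, I)
  for (i in seq_len(I - 1L)) {
    for (j in (i + 1L):I) {
      R[i, j] <- R[j, i] <- .tetrachoric_pair(responses[, i], responses[, j])
    }
  }
  dimnames(R) <- list(colnames(responses), colnames(responses))
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 1e-6) {
    v <- pmax(e$values, 1e-6)
    R <- e$vectors %*% diag(v) %*% t(e$vectors)
    d <- 1 / sqrt(diag(R))
    R <- R * tcrossprod(d)
    dimnames(R) <- list(colnames(responses), colnames(responses))
  }
  R
}

# quartimin criterion value and gradient (oblimin with gamma = 0)
.vgq_quartimin <- function(L) {
  k <- ncol(L)
  N <- matrix(1, k, k) - diag(k)
  L2 <- L^2
  X <- L2 %*% N
  list(f = sum(L2 * X) / 4, G = L * X)
}

# Oblique gradient-projection rotation to the quartimin criterion.
.oblimin_rotate <- function(A, max_iter = 500L, tol = 1e-6) {
  k <- ncol(A)
  Tm <- diag(k)
  al <- 1
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  vg <- .vgq_quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$G %*% Ti)
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (half in 1:20) {
      X <- Tm - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vg <- .vgq_quartimin(L)
      if (vg$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt
    f <- vg$f
    G <- -t(t(L) %*% vg$G %*% Ti)
  }
  list(loadings = L, Phi = t(Tm) %*% Tm)
}

#' Minimum-residual factor analysis of a correlation matrix
#'
#' Minres extraction: communalities are chosen to minimise the off-diagonal
#' residuals of the reduced correlation matrix, whose leading eigenstructure
#' gives the loadings. The per-factor variance share is the sum of squared
#' unrotated loadings divided by the number of items; shares are reported in
#' non-increasing order. With `rotation = "oblimin"` and two or more
#' factors, loadings are obliquely rotated by the quartimin criterion
#' (rotation with a single factor is a no-op).
#'
#' @param R correlation matrix (e.g. from [tetrachoric_matrix()]).
#' @param n_factors number of factors, at least 1 and fewer than the items.
#' @param rotation `"none"` or `"oblimin"`.
#' @param max_iter maximum optimizer iterations.
#' @return List of class `factor_solution`: `loadings` (rotated if
#'   requested), `unrotated`, `communalities`, `uniquenesses`,
#'   `variance_share`, `Phi` (factor correlations, oblique case),
#'   `rotation`, `converged`.
#' @export
factor_analysis <- function(R, n_factors = 1L, rotation = c("none", "oblimin"),
                            max_iter = 1000L) {
  rotation <- match.arg(rotation)
  I <- ncol(R)
  stopifnot(isSymmetric(unname(R), tol = 1e-8), n_factors >= 1L,
            n_factors < I)
  eig_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (eig_min < -1e-8)
    stop("correlation matrix is not positive semidefinite")

  lead_load <- function(psi) {
    Rs <- R
    diag(Rs) <- 1 - psi
    e <- eigen(Rs, symmetric = TRUE)
    v <- pmax(e$values[seq_len(n_factors)], 0)
    e$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(sqrt(v), n_factors)
  }
  offdiag_resid <- function(psi) {
    L <- lead_load(psi)
    Res <- R - tcrossprod(L)
    diag(Res) <- 0
    sum(Res^2)
  }
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, I))
  psi0 <- pmin(pmax(1 - smc, 0.05), 0.995)
  opt <- stats::optim(psi0, offdiag_resid, method = "L-BFGS-B",
                      lower = 0.005, upper = 0.995,
                      control = list(maxit = max_iter))
  if (opt$convergence != 0)
    stop("minres extraction did not converge (code ", opt$convergence,
         "): ", opt$message)
  A <- lead_load(opt$par)
  colnames(A) <- paste0("F", seq_len(n_factors))
  rownames(A) <- colnames(R)
  share <- colSums(A^2) / I
  ord <- order(share, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  share <- share[ord]
  colnames(A) <- paste0("F", seq_len(n_factors))
  names(share) <- colnames(A)

  loadings <- A
  Phi <- diag(n_factors)
  if (rotation == "oblimin" && n_factors >= 2L) {
    rot <- .oblimin_rotate(A)
    loadings <- rot$loadings
    Phi <- rot$Phi
    dimnames(loadings) <- dimnames(A)
  }
  comm <- rowSums(A^2)
  structure(list(loadings = loadings, unrotated = A,
                 communalities = comm, uniquenesses = 1 - comm,
                 variance_share = share, Phi = Phi,
                 rotation = rotation, converged = TRUE),
            class = "factor_solution")
}

#' Item-retention filter
#'
#' An item is retained when it loads adequately on the dominant factor
#' (loading at or above `loading_min`) or shows adequate communality
#' (at or above `communality_min`), and in addition discriminates adequately
#' (GGUM discrimination at or above `alpha_min`).
#'
#' @param loadings named numeric vector of dominant-factor loadings
#'   (absolute values are used).
#' @param communalities named numeric vector aligned with `loadings`.
#' @param alphas named numeric vector of discrimination estimates, aligned.
#' @param loading_min,communality_min,alpha_min thresholds
#'   (defaults 0.3, 0.2, 0.7).
#' @return Character vector of retained item labels, in input order.
#' @export
retention_filter <- function(loadings, communalities, alphas,
                             loading_min = 0.3, communality_min = 0.2,
                             alpha_min = 0.7) {
  if (length(loadings) != length(communalities) ||
      length(loadings) != length(alphas))
    stop("loadings, communalities and alphas must be aligned")
  if (!is.null(names(loadings)) && !is.null(names(alphas)) &&
      !identical(names(loadings), names(alphas)))
    stop("loadings and alphas are labelled with different items")
  keep <- (abs(loadings) >= loading_min | communalities >= communality_min) &
    alphas >= alpha_min
  labs <- names(loadings) %||% as.character(seq_along(loadings))
  labs[keep]
}

#' Dimensionality and retention report
#'
#' Runs the full dimensionality step on a response matrix: tetrachoric
#' correlations, a two-factor minres solution for the dominance diagnostic
#' (is the leading variance share above `dominance_min`?), a one-factor
#' refit for loadings and communalities, and the retention filter against
#' the supplied discrimination estimates.
#'
#' @param responses binary response matrix.
#' @param alphas named vector of GGUM discrimination estimates per item.
#' @param dominance_min variance share the dominant factor must exceed for
#'   the item set to count as unidimensional (default 0.20).
#' @param ... thresholds passed to [retention_filter()].
#' @return List with `table` (item, loading, communality, alpha, retained),
#'   `variance_shares` (two-factor diagnostic), `unidimensional`, `retained`.
#' @export
dimensionality_report <- function(responses, alphas, dominance_min = 0.20,
                                  ...) {
  R <- tetrachoric_matrix(responses)
  two <- factor_analysis(R, n_factors = 2L, rotation = "oblimin")
  one <- factor_analysis(R, n_factors = 1L)
  load1 <- one$loadings[, 1L]
  alphas <- alphas[colnames(responses)]
  retained <- retention_filter(load1, one$communalities, alphas, ...)
  tab <- data.frame(item = colnames(responses), loading = unname(load1),
                    communality = unname(one$communalities),
                    alpha = unname(alphas),
                    retained = as.integer(colnames(responses) %in% retained),
                    stringsAsFactors = FALSE)
  list(table = tab, variance_shares = two$variance_share,
       unidimensional = two$variance_share[1L] > dominance_min,
       retained = retained)
}
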