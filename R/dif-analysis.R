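# Likelihood-ratio tests of differential item functioning (DIF).
#
# An item shows DIF when respondents from different groups with the same
# latent-trait level have different response probabilities. The test
# compares a constrained two-group fit (the studied item's parameters equal
# across groups, the metric linked through anchor items) against a fit that
# frees the studied item's alpha, delta and tau in one group; twice the
# log-likelihood gain is referred to chi-square with 3 df.

# Two-group EM with a per-item free/shared mask. resp_list: list of two
# binary matrices with identical columns. free: logical per item; TRUE means
# the item gets group-specific parameters. Both groups share the N(0,1)
# trait metric. Returns total marginal log-likelihood and per-group
# parameter matrices.
.fit_em_groups <- function(resp_list, free, cfg, start) {
  nodes <- ggum_quadrature(cfg$quad_nodes, cfg$quad_bounds)$nodes
  logw <- log(ggum_quadrature(cfg$quad_nodes, cfg$quad_bounds)$weights)
  pats <- lapply(resp_list, .collapse_patterns)
  parms <- list(start, start)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  I <- ncol(resp_list[[1L]])
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    es <- Map(function(p, pat) .estep(p, pat$Xp, pat$counts, nodes, logw),
              parms, pats)
    ll <- sum(vapply(es, `[[`, numeric(1), "ll"))
    r1 <- Map(function(e, pat) t(pat$Xp) %*% e$post, es, pats)
    Nq <- lapply(es, function(e) colSums(e$post))
    new <- parms
    for (i in seq_len(I)) {
      if (free[i]) {
        for (g in 1:2)
          new[[g]][i, ] <- .mstep_item(parms[[g]][i, ], r1[[g]][i, ],
                                       Nq[[g]] - r1[[g]][i, ], nodes, cfg)
      } else {
        upd <- .mstep_item(parms[[1L]][i, ],
                           r1[[1L]][i, ] + r1[[2L]][i, ],
                           (Nq[[1L]] - r1[[1L]][i, ]) +
                             (Nq[[2L]] - r1[[2L]][i, ]), nodes, cfg)
        new[[1L]][i, ] <- upd; new[[2L]][i, ] <- upd
      }
    }
    dpar <- max(abs(new[[1L]] - parms[[1L]]), abs(new[[2L]] - parms[[2L]]))
    dll <- abs(ll - ll_old) / (abs(ll) + .Machine$double.eps)
    parms <- new
    if (iter > 1L && dll < cfg$tol_rel_ll && dpar < cfg$tol_par) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  ll <- sum(vapply(seq_len(2L), function(g)
    .ll_only(parms[[g]], pats[[g]]$Xp, pats[[g]]$counts, nodes, logw),
    numeric(1)))
  list(ll = ll, parms = parms, converged = converged, n_iterations = iter)
}

.split_groups <- function(responses, groups) {
  groups <- as.character(groups)
  if (length(groups) != nrow(responses))
    stop("groups must have one label per respondent")
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups are required, got ",
                              length(lev))
  lapply(lev, function(g) responses[groups == g, , drop = FALSE])
}

#' Likelihood-ratio DIF test for every item
#'
#' For each studied item, a constrained two-group fit (item parameters equal
#' across groups; any non-anchor items other than the studied one are freed)
#' is compared with a fit additionally freeing the studied item's
#' discrimination, location and threshold in the second group. The statistic
#' is twice the marginal log-likelihood difference, with 3 degrees of
#' freedom; p-values are Benjamini-Hochberg adjusted across items. An item is
#' flagged when the adjusted p-value falls below `level`. Non-convergent
#' sub-fits mark the item untestable rather than being dropped silently.
#'
#' @param responses binary matrix, respondents x items.
#' @param groups two-level label per respondent (e.g. sex, or the 7-9 vs
#'   10-12 age bands).
#' @param config list: `level` (0.05), `anchors` (item labels linking the
#'   group metrics; default all items, the all-other scheme), `items`
#'   (studied items; default all), plus any [fit_ggum_mml()] option.
#' @return Data frame, one row per studied item: `item`, `statistic`, `df`,
#'   `p_value`, `adjusted_p`, `flagged`, `converged`, and the group-specific
#'   estimates `alpha_A/B`, `delta_A/B`, `tau_A/B` from the freed fit.
#' @export
dif_test <- function(responses, groups, config = list()) {
  level <- config$level %||% 0.05
  anchors <- config$anchors %||% colnames(responses)
  studied <- config$items %||% colnames(responses)
  cfg <- .calib_config(config[setdiff(names(config),
                                      c("level", "anchors", "items"))])
  responses <- as.matrix(responses)
  storage.mode(responses) <- "double"
  resp_list <- .split_groups(responses, groups)
  ns <- vapply(resp_list, nrow, integer(1))
  if (any(ns < 100L))
    warning("group sizes below 100 (", paste(ns, collapse = ", "),
            "); DIF tests may be unstable")
  for (g in 1:2) .check_binary_items(resp_list[[g]])
  items <- colnames(responses)
  bad <- setdiff(c(anchors, studied), items)
  if (length(bad)) stop("unknown item label(s): ", paste(bad, collapse = ", "))

  pooled <- suppressWarnings(fit_ggum_mml(responses, config = cfg))
  start <- as.matrix(pooled$estimates[, c("alpha", "delta", "tau")])
  cfg_warm <- cfg

  free_base <- !(items %in% anchors)
  # constrained fit shared across studied items whenever the baseline free
  # set does not depend on the studied item (the all-other scheme)
  fit0_cache <- NULL
  get_fit0 <- function(free0) {
    if (!any(free0 != free_base)) {
      if (is.null(fit0_cache))
        fit0_cache <<- .fit_em_groups(resp_list, free0, cfg_warm, start)
      fit0_cache
    } else .fit_em_groups(resp_list, free0, cfg_warm, start)
  }

  rows <- lapply(studied, function(it) {
    j <- match(it, items)
    free0 <- free_base; free0[j] <- FALSE
    free1 <- free0; free1[j] <- TRUE
    fit0 <- get_fit0(free0)
    fit1 <- .fit_em_groups(resp_list, free1, cfg_warm, start)
    ok <- fit0$converged && fit1$converged
    stat <- if (ok) max(0, 2 * (fit1$ll - fit0$ll)) else NA_real_
    data.frame(item = it, statistic = stat, df = 3L,
               p_value = if (ok) stats::pchisq(stat, 3L, lower.tail = FALSE)
                         else NA_real_,
               converged = ok,
               alpha_A = fit1$parms[[1L]][j, 1L],
               delta_A = fit1$parms[[1L]][j, 2L],
               tau_A = fit1$parms[[1L]][j, 3L],
               alpha_B = fit1$parms[[2L]][j, 1L],
               delta_B = fit1$parms[[2L]][j, 2L],
               tau_B = fit1$parms[[2L]][j, 3L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$flagged <- out$adjusted_p < level
  out[c("item", "statistic", "df", "p_value", "adjusted_p", "flagged",
        "converged", "alpha_A", "delta_A", "tau_A",
        "alpha_B", "delta_B", "tau_B")]
}

#' Select anchor items by iterative purification
#'
#' Starts with every item anchored, tests each item for DIF under the
#' current anchor set, and removes the largest-statistic item whose raw
#' p-value falls below `level`; repeated until no removal occurs or
#' `max_rounds` is reached. Errors if fewer than two anchors would remain.
#'
#' @inheritParams dif_test
#' @param config as in [dif_test()], plus `max_rounds` (default 3).
#' @return Character vector of anchor item labels.
#' @export
anchor_select <- function(responses, groups, config = list()) {
  level <- config$level %||% 0.05
  max_rounds <- config$max_rounds %||% 3L
  anchors <- colnames(responses)
  for (round in seq_len(max_rounds)) {
    cfg <- config
    cfg$anchors <- anchors
    cfg$max_rounds <- NULL
    res <- dif_test(responses, groups, cfg)
    cand <- res[!is.na(res$p_value) & res$p_value < level &
                  res$item %in% anchors, , drop = FALSE]
    if (nrow(cand) == 0L) break
    drop <- cand$item[which.max(cand$statistic)]
    anchors <- setdiff(anchors, drop)
    if (length(anchors) < 2L)
      stop("purification removed too many anchors; fewer than 2 remain")
  }
  anchors
}

`%||%` <- function(a, b) if (is.null(a)) b else a
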