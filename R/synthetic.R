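# Synthetic-data generator emulating the study conditions: N(0,1) latent
# traits, binary item responses from the reference unfolding model, food-level
# recall records realizing those responses, optional implausible reporters,
# optional planted DIF, and a stratified two-stage survey design.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator with the study
#' conditions as defaults: 6,399 respondents, the published 11-item
#' parameter sets (common threshold -1), and a standard-normal latent trait.
#'
#' @param n_respondents number of children (default 6399).
#' @param model generating [ggum_model()] (default [mesa_reference_model()]).
#' @param seed integer seed, mandatory; identical configurations yield
#'   identical data.
#' @param dif_spec optional planted DIF: list with `item`, `parameter`
#'   (`"alpha"`, `"delta"` or `"tau"`) and `shift`, applied to group B's
#'   generating parameters.
#' @param group_fraction fraction of respondents assigned to group B.
#' @param implausible_spec optional list `n_low`, `n_high` (and optionally
#'   `low_count`, `high_count`, defaults 3 and 60): extra children appended
#'   with implausibly few / many food rows, the reports the cleaning rules
#'   are meant to remove.
#' @param nuisance_rate endorsement rate of the 7 occasion-class items not in
#'   the generating model (default 0.5, emulating foods like bread whose
#'   consumption varies little with meal quality).
#' @param skip_prob named vector of occasion-skipping probabilities (a
#'   skipped occasion zeroes its three items); default none.
#' @param foods_per_cell integer range: how many distinct foods realize each
#'   positive occasion-class indicator (default 1 to 3).
#' @return List of class `mesa_sim_config`.
#' @export
simulation_config <- function(n_respondents = 6399L,
                              model = mesa_reference_model(),
                              seed,
                              dif_spec = NULL,
                              group_fraction = 0.5,
                              implausible_spec = NULL,
                              nuisance_rate = 0.5,
                              skip_prob = NULL,
                              foods_per_cell = c(1L, 3L)) {
  if (missing(seed) || !is.finite(seed)) stop("an integer seed is mandatory")
  stopifnot(inherits(model, "ggum_model"), n_respondents >= 1L,
            group_fraction > 0, group_fraction < 1,
            nuisance_rate >= 0, nuisance_rate <= 1)
  if (any(vapply(model$items, `[[`, numeric(1), "alpha") <= 0))
    stop("all generating discriminations must be positive")
  if (!is.null(dif_spec)) {
    stopifnot(is.list(dif_spec),
              dif_spec$item %in% item_ids(model),
              dif_spec$parameter %in% c("alpha", "delta", "tau"),
              is.finite(dif_spec$shift))
  }
  if (!is.null(skip_prob)) {
    bad <- setdiff(names(skip_prob), eating_occasions())
    if (length(bad)) stop("unknown occasion(s) in skip_prob: ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(implausible_spec)) {
    implausible_spec$low_count <- implausible_spec$low_count %||% 3L
    implausible_spec$high_count <- implausible_spec$high_count %||% 60L
  }
  structure(list(n_respondents = as.integer(n_respondents), model = model,
                 seed = as.integer(seed), dif_spec = dif_spec,
                 group_fraction = group_fraction,
                 implausible_spec = implausible_spec,
                 nuisance_rate = nuisance_rate, skip_prob = skip_prob,
                 foods_per_cell = as.integer(foods_per_cell)),
            class = "mesa_sim_config")
}

.parmat_from_model <- function(model) {
  t(vapply(model$items,
           function(it) c(it$alpha, it$delta, it$tau[1L]), numeric(3)))
}

#' Simulate latent traits and item responses
#'
#' Draws `theta_j ~ N(0, 1)` (the calibration-scale trait distribution) and
#' one binary response per item from the unfolding response probabilities.
#' Group labels are assigned independently of theta; when `dif_spec` is set,
#' group B's responses to the affected item are generated under the shifted
#' parameter.
#'
#' @param config a [simulation_config()].
#' @return List with `theta`, `responses` (children x items, item ids as
#'   column names), and `groups` (factor "A"/"B").
#' @export
simulate_responses <- function(config) {
  stopifnot(inherits(config, "mesa_sim_config"))
  model <- config$model
  N <- config$n_respondents
  ids <- sprintf("c%05d", seq_len(N))
  .with_seed(config$seed, {
    theta <- stats::rnorm(N, model$trait_mean, model$trait_sd)
    groups <- factor(ifelse(stats::runif(N) < config$group_fraction, "B", "A"),
                     levels = c("A", "B"))
    parmat <- .parmat_from_model(model)
    P <- .prob1_bank(parmat, theta)
    if (!is.null(config$dif_spec)) {
      ds <- config$dif_spec
      j <- match(ds$item, item_ids(model))
      parmat_b <- parmat
      col <- match(ds$parameter, c("alpha", "delta", "tau"))
      parmat_b[j, col] <- parmat_b[j, col] + ds$shift
      if (parmat_b[j, 1L] <= 0)
        stop("DIF shift makes the discrimination non-positive")
      Pb <- .prob1_bank(parmat_b[j, , drop = FALSE], theta)[, 1L]
      P[groups == "B", j] <- Pb[groups == "B"]
    }
    X <- matrix(as.integer(stats::runif(length(P)) < P), nrow = N,
                dimnames = list(ids, item_ids(model)))
    list(theta = stats::setNames(theta, ids), responses = X, groups = groups)
  })
}

#' Simulate food-level recall records
#'
#' Realizes item responses as food rows, the constructed inverse of
#' [build_items()]: an 18-item response matrix is generated (the modelled
#' items from the unfolding model, the remaining occasion-class items as
#' Bernoulli nuisance items), occasions are optionally skipped, and every
#' positive occasion-class indicator is realized as one to three distinct
#' foods drawn from that class's vocabulary. Children configured as
#' implausible reporters are appended with a fixed number of random food
#' rows. Rebuilding items from the returned records reproduces the
#' generating matrix exactly for every child who reports at least one food
#' (a child whose row is all zero reports nothing and so is absent from the
#' records).
#'
#' @param config a [simulation_config()].
#' @return List with `records` (long data frame `child_id,occasion,food`),
#'   `responses` (the generating 18-item matrix, core children), `theta`,
#'   `groups`, and `implausible_ids`.
#' @export
simulate_food_records <- function(config) {
  stopifnot(inherits(config, "mesa_sim_config"))
  sim <- simulate_responses(config)
  layout <- mesa_item_layout()
  N <- config$n_respondents
  ids <- rownames(sim$responses)
  .with_seed(config$seed + 1L, {
    X18 <- matrix(0L, N, nrow(layout), dimnames = list(ids, layout$item))
    X18[, colnames(sim$responses)] <- sim$responses
    nuisance <- setdiff(layout$item, colnames(sim$responses))
    for (it in nuisance)
      X18[, it] <- as.integer(stats::runif(N) < config$nuisance_rate)
    if (!is.null(config$skip_prob)) {
      for (occ in names(config$skip_prob)) {
        skip <- stats::runif(N) < config$skip_prob[[occ]]
        X18[skip, layout$item[layout$occasion == occ]] <- 0L
      }
    }
    map <- default_nova_map()
    vocab <- split(map$food, map$class)
    cells <- which(X18 == 1L, arr.ind = TRUE)
    kvals <- seq(config$foods_per_cell[1L], config$foods_per_cell[2L])
    k <- if (length(kvals) == 1L) rep(kvals, nrow(cells))
         else sample(kvals, nrow(cells), replace = TRUE)
    cls <- layout$class[cells[, 2L]]
    k <- pmin(k, lengths(vocab)[cls])
    foods <- unlist(lapply(seq_len(nrow(cells)), function(r)
      sample(vocab[[cls[r]]], k[r])))
    records <- data.frame(
      child_id = rep(ids[cells[, 1L]], k),
      occasion = rep(layout$occasion[cells[, 2L]], k),
      food = foods, stringsAsFactors = FALSE)
    implausible_ids <- character(0)
    if (!is.null(config$implausible_spec)) {
      sp <- config$implausible_spec
      combos <- expand.grid(occasion = eating_occasions(), food = map$food,
                            stringsAsFactors = FALSE)
      extra <- list()
      n_low <- sp$n_low %||% 0L
      n_high <- sp$n_high %||% 0L
      mk <- function(id, count) {
        pick <- combos[sample.int(nrow(combos), count), , drop = FALSE]
        data.frame(child_id = id, occasion = pick$occasion, food = pick$food,
                   stringsAsFactors = FALSE)
      }
      if (n_low > 0L)
        extra <- c(extra, lapply(sprintf("xlow%03d", seq_len(n_low)),
                                 mk, count = sp$low_count))
      if (n_high > 0L)
        extra <- c(extra, lapply(sprintf("xhigh%03d", seq_len(n_high)),
                                 mk, count = sp$high_count))
      if (length(extra)) {
        extra <- do.call(rbind, extra)
        implausible_ids <- unique(extra$child_id)
        records <- rbind(records, extra)
      }
    }
    records <- records[order(match(records$child_id, unique(records$child_id))), ]
    rownames(records) <- NULL
    list(records = records, responses = X18, theta = sim$theta,
         groups = sim$groups, implausible_ids = implausible_ids)
  })
}

#' Simulate a stratified two-stage survey design
#'
#' Children nested in clusters (classes) within strata (survey-year by
#' school combinations), with positive lognormal cluster weights.
#'
#' @param n_strata,clusters_per_stratum,children_per_cluster design sizes.
#' @param seed integer seed.
#' @param weight_sd SD of the log cluster weights (0 gives equal weights).
#' @return Data frame with `child_id`, `stratum`, `cluster`, `weight`; one
#'   row per child.
#' @export
simulate_survey_design <- function(n_strata = 2L, clusters_per_stratum = 4L,
                                   children_per_cluster = 25L, seed,
                                   weight_sd = 0.3) {
  stopifnot(!missing(seed))
  .with_seed(seed, {
    strata <- sprintf("s%02d", seq_len(n_strata))
    grid <- expand.grid(cluster_i = seq_len(clusters_per_stratum),
                        stratum = strata, stringsAsFactors = FALSE)
    grid$cluster <- sprintf("%s_c%02d", grid$stratum, grid$cluster_i)
    grid$weight <- exp(stats::rnorm(nrow(grid), 0, weight_sd))
    out <- grid[rep(seq_len(nrow(grid)), each = children_per_cluster), ]
    out$child_id <- sprintf("c%05d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out[c("child_id", "stratum", "cluster", "weight")]
  })
}
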