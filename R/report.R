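# Population application of the calibrated scale: survey-weighted level
# prevalence with stratified cluster-bootstrap confidence intervals, and the
# top-k foods per eating occasion within each meal-quality level.

#' Survey-weighted prevalence of meal-quality levels
#'
#' Point estimates are weighted proportions of children in each level.
#' Confidence intervals come from a stratified cluster bootstrap: clusters
#' are resampled with replacement within strata (respecting the two-stage
#' design in which classes, not children, were the sampling units) and the
#' weighted proportions recomputed per replicate. Strata containing a single
#' cluster are collapsed into one pooled stratum, with a warning.
#'
#' @param levels factor of per-child levels (healthy/mixed/unhealthy).
#' @param design data frame aligned with `levels`: columns `stratum`,
#'   `cluster`, `weight` (positive).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf_level confidence level (default 0.95).
#' @return Data frame: `level`, `proportion`, `ci_low`, `ci_high`, `n`,
#'   `method`.
#' @export
level_prevalence <- function(levels, design, n_boot = 1000L, seed,
                             conf_level = 0.95) {
  stopifnot(!missing(seed), is.data.frame(design),
            all(c("stratum", "cluster", "weight") %in% names(design)))
  if (length(levels) != nrow(design))
    stop("levels and design must be aligned row by row")
  if (any(design$weight <= 0)) stop("weights must be positive")
  levels <- factor(levels, levels = c("healthy", "mixed", "unhealthy"))
  if (anyNA(levels)) stop("levels must be healthy, mixed or unhealthy")

  n_cl <- tapply(design$cluster, design$stratum,
                 function(x) length(unique(x)))
  singles <- names(n_cl)[n_cl < 2L]
  stratum <- as.character(design$stratum)
  if (length(singles)) {
    warning("collapsing single-cluster strata into one pooled stratum: ",
            paste(singles, collapse = ", "))
    stratum[stratum %in% singles] <- ".collapsed"
  }

  # per-cluster weighted level totals; bootstrap replicates only resample
  # and sum these rows
  key <- paste(stratum, design$cluster, sep = "\r")
  wtab <- rowsum(design$weight *
                   (outer(as.character(levels), levels(levels), `==`) * 1), key)
  colnames(wtab) <- levels(levels)
  cl_stratum <- sub("\r.*$", "", rownames(wtab))
  point <- colSums(wtab) / sum(wtab)

  by_str <- split(seq_len(nrow(wtab)), cl_stratum)
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      rows <- unlist(lapply(by_str, function(idx)
        idx[sample.int(length(idx), replace = TRUE)]), use.names = FALSE)
      tot <- colSums(wtab[rows, , drop = FALSE])
      tot / sum(tot)
    }, numeric(3L))
  })
  a <- (1 - conf_level) / 2
  ci <- apply(boot, 1L, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(level = levels(levels), proportion = unname(point),
             ci_low = ci[1L, ], ci_high = ci[2L, ],
             n = as.integer(table(levels)),
             method = sprintf("stratified cluster bootstrap (%d reps)", n_boot),
             stringsAsFactors = FALSE)
}

#' Top foods per eating occasion within each meal-quality level
#'
#' For every occasion-level combination, the `k` foods reported by the
#' largest percentage of the level's children (a child counts once per food
#' per occasion regardless of duplicates; the denominator is all children in
#' the level). Ties are broken alphabetically. Levels with no children yield
#' no rows.
#'
#' @param records food-record data frame (`child_id`, `occasion`, `food`).
#' @param levels per-child levels: a data frame `child_id`, `level`.
#' @param k number of foods per block (default 5).
#' @return Data frame: `occasion`, `level`, `rank`, `food`, `pct`
#'   (percentage of the level's children reporting the food at the occasion).
#' @export
top_foods <- function(records, levels, k = 5L) {
  stopifnot(is.data.frame(levels),
            all(c("child_id", "level") %in% names(levels)))
  .check_records(records)
  extra <- setdiff(records$child_id, levels$child_id)
  if (length(extra))
    stop("records contain children without a level: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  lev <- factor(levels$level, levels = c("healthy", "mixed", "unhealthy"))
  n_level <- table(lev)
  rec <- unique(records[c("child_id", "occasion", "food")])
  rec$level <- lev[match(rec$child_id, levels$child_id)]
  out <- list()
  for (occ in eating_occasions()) {
    for (lv in levels(lev)) {
      if (n_level[[lv]] == 0L) next
      sub <- rec[rec$occasion == occ & rec$level == lv, , drop = FALSE]
      if (nrow(sub) == 0L) next
      cnt <- table(sub$food)
      pct <- 100 * as.numeric(cnt) / n_level[[lv]]
      ord <- order(-pct, names(cnt))
      take <- utils::head(ord, k)
      out[[length(out) + 1L]] <- data.frame(
        occasion = occ, level = lv, rank = seq_along(take),
        food = names(cnt)[take], pct = pct[take], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(occasion = character(), level = character(),
                      rank = integer(), food = character(), pct = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Run the full scale-development pipeline
#'
#' Orchestrates the nine development steps on simulated or supplied data:
#' food records -> cleaning -> 18 binary items -> 18-item calibration ->
#' dimensionality and retention -> refit of the retained scale (oriented so
#' MPF items sit on the negative, healthy side) -> scale table and test
#' information -> EAP scores and levels -> optional DIF -> weighted level
#' prevalence and top foods. Each stage writes its artifact to `out_dir`
#' (when given) and logs a stage-tagged message; a failure stops with the
#' stage named.
#'
#' @param config list (or path to a YAML file holding one): either `sim`
#'   (arguments for [simulation_config()], `seed` required) or `records` (a
#'   data frame or CSV path); optional `design` (survey-design data frame),
#'   `groups` (two-level per-child labels for DIF; skipped with a warning
#'   when absent), `out_dir`, `calib` ([fit_ggum_mml()] config), `dif`
#'   ([dif_test()] config), `retention` (thresholds for [retention_filter()]),
#'   `n_boot` and `seed` for the prevalence bootstrap.
#' @return Invisible list with every stage artifact: `records`, `clean_log`,
#'   `responses18`, `fit18`, `dimensionality`, `retained`, `fit`, `model`,
#'   `scale_table`, `information`, `scores`, `dif`, `prevalence`,
#'   `top_foods`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir
  emit <- function(name, obj, writer) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      writer(obj, file.path(out_dir, name))
    }
  }
  wcsv <- function(obj, path) utils::write.csv(obj, path, row.names = FALSE)
  stage <- function(name, expr) {
    message(sprintf("[%s] running", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  truth <- NULL
  if (is.null(config$records)) {
    if (is.null(config$sim))
      stop("pipeline config must provide either records or sim")
    truth <- stage("simulate",
                   simulate_food_records(do.call(simulation_config,
                                                 config$sim)))
  }
  records <- stage("records", {
    if (!is.null(config$records)) {
      if (is.character(config$records)) read_food_records(config$records)
      else .check_records(config$records)
    } else truth$records
  })
  emit("records.csv", records, wcsv)

  cleaned <- stage("clean", clean_reports(records))
  emit("exclusions.csv", cleaned$log, wcsv)

  responses18 <- stage("build_items", build_items(cleaned$records))
  emit("responses18.csv", responses18, function(o, p) write_response_matrix(o, p))

  fit18 <- stage("calibrate_18", suppressWarnings(
    fit_ggum_mml(responses18, config$calib %||% list())))

  dimrep <- stage("dimensionality", {
    alphas <- stats::setNames(fit18$estimates$alpha, fit18$estimates$item)
    do.call(dimensionality_report,
            c(list(responses = responses18, alphas = alphas),
              config$retention %||% list()))
  })
  emit("dimensionality.csv", dimrep$table, wcsv)
  if (!dimrep$unidimensional)
    warning("dominant-factor variance share ",
            sprintf("%.3f", dimrep$variance_shares[1L]),
            " is below the unidimensionality threshold")

  retained <- dimrep$retained
  if (length(retained) < 2L)
    stop("pipeline stage 'retention' failed: fewer than 2 items retained")

  fit <- stage("calibrate_retained", {
    layout <- mesa_item_layout()
    mpf <- retained[retained %in% layout$item[layout$class == "MPF"]]
    cfg <- config$calib %||% list()
    if (length(mpf)) cfg$orientation <- list(item = mpf[1L], sign = -1)
    suppressWarnings(fit_ggum_mml(subset_items(responses18, retained), cfg))
  })
  emit("calibration.csv", fit$estimates, wcsv)
  emit("model.json", fit$model, function(o, p) write_model_json(o, p))

  stable <- stage("scale_table", scale_table(fit$model))
  emit("scale_table.csv", stable, wcsv)
  info <- stage("information",
                test_information(fit$model, seq(-4, 4, by = 0.05)))
  emit("information.csv",
       data.frame(theta = info$theta, information = info$information,
                  se = info$se), wcsv)

  scores <- stage("score", eap_scores(fit$model, subset_items(responses18,
                                                              retained)))
  emit("scores.csv", scores, wcsv)

  dif <- NULL
  if (!is.null(config$groups) || !is.null(truth$groups)) {
    dif <- stage("dif", {
      g <- config$groups %||%
        stats::setNames(as.character(truth$groups),
                        rownames(truth$responses))
      dif_test(subset_items(responses18, retained),
               g[rownames(responses18)], config$dif %||% list())
    })
    emit("dif_report.csv", dif, wcsv)
  } else {
    warning("no group labels supplied; DIF stage skipped")
  }

  prevalence <- NULL
  if (!is.null(config$design)) {
    prevalence <- stage("prevalence", {
      d <- config$design
      d <- d[match(scores$child_id, d$child_id), , drop = FALSE]
      if (anyNA(d$weight)) stop("design does not cover every scored child")
      level_prevalence(scores$level, d,
                       n_boot = config$n_boot %||% 1000L,
                       seed = (config$seed %||% 1L) + 7L)
    })
    emit("prevalence.csv", prevalence, wcsv)
  }

  tf <- stage("top_foods",
              top_foods(cleaned$records,
                        scores[c("child_id", "level")]))
  emit("top_foods.csv", tf, wcsv)

  invisible(list(records = records, clean_log = cleaned$log,
                 responses18 = responses18, fit18 = fit18,
                 dimensionality = dimrep, retained = retained, fit = fit,
                 model = fit$model, scale_table = stable, information = info,
                 scores = scores, dif = dif, prevalence = prevalence,
                 top_foods = tf))
}
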