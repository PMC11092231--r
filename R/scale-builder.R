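#' Linear transformation between calibration and reporting scales
#'
#' Item locations, crossing points and person scores are estimated on the
#' calibration scale (trait mean 0, SD 1) and reported on a mean-100 / SD-10
#' scale to avoid negative and decimal values.
#'
#' @param x numeric values on the calibration scale.
#' @param spec named vector `c(mean =, sd =)` of the reporting scale.
#' @return `to_reporting_scale`: `mean + sd * x`; `to_calibration_scale` is
#'   its inverse.
#' @examples
#' to_reporting_scale(c(-1.8, 0, 1.8))  # 82 100 118
#' @export
to_reporting_scale <- function(x, spec = c(mean = 100, sd = 10)) {
  stopifnot(all(is.finite(x)))
  unname(spec["mean"]) + unname(spec["sd"]) * x
}

#' @rdname to_reporting_scale
#' @export
to_calibration_scale <- function(x, spec = c(mean = 100, sd = 10)) {
  stopifnot(all(is.finite(x)))
  (x - unname(spec["mean"])) / unname(spec["sd"])
}

#' Assign meal-quality levels from reporting-scale scores
#'
#' Scores below the lower cut-off are `healthy`, above the upper cut-off
#' `unhealthy`, and in the closed interval between them (boundaries included)
#' `mixed`.
#'
#' @param score numeric scores on the reporting scale.
#' @param cutoffs named vector `c(lower = 95, upper = 101)`.
#' @return Factor with levels healthy, mixed, unhealthy.
#' @export
assign_level <- function(score, cutoffs = c(lower = 95, upper = 101)) {
  stopifnot(all(is.finite(score)))
  lo <- unname(cutoffs["lower"]); hi <- unname(cutoffs["upper"])
  out <- ifelse(score < lo, "healthy", ifelse(score > hi, "unhealthy", "mixed"))
  factor(out, levels = c("healthy", "mixed", "unhealthy"))
}

#' 0.5-crossing points of a dichotomous item curve
#'
#' The trait values where the consumption and non-consumption probability
#' curves intersect, i.e. where P(consumption) = 0.5. The consumption curve
#' is unimodal and symmetric about the item location, so either both
#' crossings exist (when the peak probability exceeds 0.5, equivalently
#' tau < 0) or neither does. Roots are located by bisection to better than
#' 1e-8 in theta.
#'
#' @param item a dichotomous [ggum_item()].
#' @return List with `item_id`, `lower` and `upper` (both `NA` when the
#'   curves never intersect).
#' @export
crossing_points <- function(item) {
  stopifnot(inherits(item, "ggum_item"))
  if (item$n_categories != 2L)
    stop("crossing points are defined for dichotomous items only")
  peak <- ggum_probability(item, item$delta, 1L)
  if (peak <= 0.5)
    return(list(item_id = item$item_id, lower = NA_real_, upper = NA_real_))
  f <- function(th) ggum_probability(item, th, 1L) - 0.5
  width <- 1
  while (f(item$delta - width) > 0) width <- width * 2
  lower <- stats::uniroot(f, c(item$delta - width, item$delta),
                          tol = 1e-12)$root
  upper <- stats::uniroot(f, c(item$delta, item$delta + width),
                          tol = 1e-12)$root
  list(item_id = item$item_id, lower = lower, upper = upper)
}

#' Solve for the unpublished threshold from a stated curve feature
#'
#' The threshold parameter tau of a dichotomous item controls the height and
#' width of the consumption region but was not published; it can be recovered
#' from a printed curve feature: either the lower 0.5-crossing or the peak
#' consumption probability. At the peak the response function reduces to
#' `P(1|delta) = exp(-alpha * tau) / (1 + exp(-alpha * tau))`, giving the
#' closed form for the peak constraint; the crossing constraint is solved by
#' monotone root bisection.
#'
#' @param alpha,delta item discrimination and location.
#' @param lower_crossing trait value of the lower 0.5-crossing (must be
#'   strictly below `delta`); supply exactly one constraint.
#' @param peak_probability consumption probability at `theta = delta`, in
#'   (0, 1).
#' @return The threshold tau (scalar).
#' @export
solve_tau <- function(alpha, delta, lower_crossing = NULL,
                      peak_probability = NULL) {
  if (is.null(lower_crossing) == is.null(peak_probability))
    stop("supply exactly one of lower_crossing or peak_probability")
  if (!is.null(peak_probability)) {
    p <- peak_probability
    if (!(p > 0 && p < 1)) stop("peak probability must be in (0, 1)")
    return(-log(p / (1 - p)) / alpha)
  }
  cst <- lower_crossing
  if (!(cst < delta)) stop("lower crossing must lie strictly below delta")
  g <- function(tau)
    ggum_probability(ggum_item("x", alpha, delta, tau), cst, 1L) - 0.5
  lo <- -1; hi <- 1
  while (g(lo) < 0) { lo <- lo * 2; if (lo < -1e3) stop("constraint infeasible") }
  while (g(hi) > 0) { hi <- hi * 2; if (hi > 1e3) stop("constraint infeasible") }
  stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}

#' Scale interpretation table
#'
#' Items ordered by transformed location, with their 0.5-crossings on both
#' scales and, for each meal-quality level, the modal response (consumption
#' vs non-consumption) evaluated at a representative score of the level: the
#' midpoint of the mixed band, and the midpoints of the outer bands truncated
#' at +/- 1.8 SD of the reporting scale (82 and 118), the region the scale
#' measures accurately.
#'
#' @param model a calibrated [ggum_model()].
#' @return Data frame, one row per item, ordered by location.
#' @export
scale_table <- function(model) {
  stopifnot(inherits(model, "ggum_model"))
  spec <- model$transformation
  lo <- unname(model$level_cutoffs["lower"])
  hi <- unname(model$level_cutoffs["upper"])
  edge <- 1.8 * unname(spec["sd"])
  reps <- c(healthy = (unname(spec["mean"]) - edge + lo) / 2,
            mixed = (lo + hi) / 2,
            unhealthy = (hi + unname(spec["mean"]) + edge) / 2)
  rows <- lapply(model$items, function(it) {
    cr <- crossing_points(it)
    p <- vapply(to_calibration_scale(reps, spec),
                function(th) ggum_probability(it, th, 1L), numeric(1))
    data.frame(item = it$item_id, delta = it$delta,
               delta_transformed = to_reporting_scale(it$delta, spec),
               lower_crossing = cr$lower, upper_crossing = cr$upper,
               lower_crossing_transformed =
                 if (is.na(cr$lower)) NA_real_ else to_reporting_scale(cr$lower, spec),
               upper_crossing_transformed =
                 if (is.na(cr$upper)) NA_real_ else to_reporting_scale(cr$upper, spec),
               modal_healthy = ifelse(p[1] > 0.5, "consumption", "non-consumption"),
               modal_mixed = ifelse(p[2] > 0.5, "consumption", "non-consumption"),
               modal_unhealthy = ifelse(p[3] > 0.5, "consumption", "non-consumption"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$delta), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trait interval where the scale meets an accuracy criterion
#'
#' Returns the maximal contiguous grid interval, around the point of peak
#' test information, on which the test meets an explicit accuracy
#' criterion — either a minimum information value, a maximum standard error,
#' or a minimum fraction of the peak information. Anchoring the interval at
#' the information peak makes stricter criteria yield nested, narrower
#' intervals. The criterion is a required input: "accurate" has no default
#' meaning.
#'
#' @param model a [ggum_model()].
#' @param criterion one-element named list: `information_min`, `se_max`, or
#'   `information_fraction` (of the grid maximum).
#' @param theta_grid evaluation grid on the calibration scale.
#' @return Named numeric `c(lower, upper)`; both `NA` when the criterion is
#'   never met.
#' @export
accurate_range <- function(model, criterion,
                           theta_grid = seq(-4, 4, by = 0.01)) {
  if (!is.list(criterion) || length(criterion) != 1L ||
      !(names(criterion) %in% c("information_min", "se_max",
                                "information_fraction")))
    stop("criterion must be a one-element named list: information_min, ",
         "se_max, or information_fraction")
  tic <- test_information(model, theta_grid)
  ok <- switch(names(criterion),
               information_min = tic$information >= criterion[[1L]],
               se_max = tic$se <= criterion[[1L]],
               information_fraction =
                 tic$information >= criterion[[1L]] * max(tic$information))
  if (!any(ok)) return(c(lower = NA_real_, upper = NA_real_))
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peak <- which.max(tic$information)
  best <- which(starts <= peak & ends >= peak & runs$values)
  if (length(best) == 0L) return(c(lower = NA_real_, upper = NA_real_))
  c(lower = theta_grid[starts[best]], upper = theta_grid[ends[best]])
}
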