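#' The six daily eating occasions
#'
#' Breakfast, morning snack, lunch, afternoon snack, dinner and evening
#' snack, in chronological order.
#' @return Character vector of length 6.
#' @export
eating_occasions <- function() {
  c("breakfast", "morning_snack", "lunch", "afternoon_snack",
    "dinner", "evening_snack")
}

#' The 32-food recall vocabulary
#'
#' The closed set of food labels a child can report at an eating occasion.
#' @return Character vector of length 32.
#' @export
webcaafe_vocabulary <- function() default_nova_map()$food

#' Default NOVA processing-class map
#'
#' Maps each of the 32 recall foods to a NOVA processing class: MPF
#' (unprocessed/minimally processed, 16 foods, e.g. rice, beans, fruit,
#' milk), PF (processed: bread, cheese) or UPF (ultra-processed, 14 foods,
#' e.g. sodas, cream cookies; yogurt is classified UPF, matching the
#' prevailing consumption of flavoured dairy drinks over natural yogurt).
#' The map ships as a plain two-column CSV so alternative classifications can
#' be swapped in via [read_nova_map()].
#'
#' @return Data frame with columns `food` and `class`.
#' @export
default_nova_map <- function() {
  read_nova_map(system.file("extdata", "nova_map.csv", package = "mesascale",
                            mustWork = TRUE))
}

#' Read a NOVA map from a two-column CSV
#'
#' @param path CSV file with header `food,class`; `class` must be one of
#'   MPF, PF, UPF and every food must appear exactly once.
#' @return Data frame with columns `food` and `class`.
#' @export
read_nova_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(sort(names(map)), c("class", "food")))
    stop("NOVA map must have exactly the columns food,class")
  if (anyDuplicated(map$food))
    stop("NOVA map assigns more than one class to: ",
         paste(unique(map$food[duplicated(map$food)]), collapse = ", "))
  bad <- setdiff(unique(map$class), c("MPF", "PF", "UPF"))
  if (length(bad)) stop("unknown NOVA class: ", paste(bad, collapse = ", "))
  map[c("food", "class")]
}

#' Layout of the 18 occasion-by-class items
#'
#' Three consumption items (MPF, PF, UPF) per eating occasion, ordered
#' breakfast to evening snack and MPF, PF, UPF within occasion, labelled
#' `i01` to `i18`.
#'
#' @return Data frame with columns `item`, `occasion`, `class`.
#' @export
mesa_item_layout <- function() {
  occ <- eating_occasions()
  data.frame(
    item = sprintf("i%02d", 1:18),
    occasion = rep(occ, each = 3L),
    class = rep(c("MPF", "PF", "UPF"), times = 6L),
    stringsAsFactors = FALSE)
}

#' Published parameter table of the 11 retained scale items
#'
#' The reference factor loadings, communalities and GGUM discrimination and
#' location estimates (with standard errors) of the 11 items retained in the
#' final meal-quality scale, in ascending order of location. Thresholds were
#' not published; see [mesa_reference_model()] for the convention used to
#' complete the item parameter sets.
#'
#' @return Data frame with columns `item`, `label`, `occasion`, `class`,
#'   `loading`, `communality`, `alpha`, `alpha_se`, `delta`, `delta_se`.
#' @export
mesa_item_table <- function() {
  utils::read.csv(system.file("extdata", "mesa_item_parameters.csv",
                              package = "mesascale", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Reference 11-item GGUM scale model
#'
#' Builds a [ggum_model()] from the published discrimination and location
#' estimates of the 11 retained items. Thresholds are unpublished, so a
#' common value is supplied (default -1, giving every item a consumption
#' region with 0.5-crossings, the shape most item curves display); pass a
#' named vector to override individual items, e.g. a small positive tau for
#' items whose consumption curve never reaches 0.5.
#'
#' @param tau threshold(s): a single number recycled to all items, or a named
#'   numeric vector keyed by item id (missing entries fall back to `default`).
#' @param default fallback threshold used when `tau` is named.
#' @return A `ggum_model` of the 11 retained items in published order.
#' @export
mesa_reference_model <- function(tau = -1, default = -1) {
  tab <- mesa_item_table()
  if (is.null(names(tau))) {
    tau_vec <- rep_len(tau, nrow(tab))
  } else {
    tau_vec <- rep_len(default, nrow(tab))
    idx <- match(names(tau), tab$item)
    if (anyNA(idx)) stop("unknown item in tau: ",
                         paste(names(tau)[is.na(idx)], collapse = ", "))
    tau_vec[idx] <- tau
  }
  items <- lapply(seq_len(nrow(tab)), function(i)
    ggum_item(tab$item[i], tab$alpha[i], tab$delta[i], tau_vec[i]))
  ggum_model(items)
}
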