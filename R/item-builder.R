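#' Classify a food into its NOVA processing class
#'
#' @param food character vector of food labels from the recall vocabulary.
#' @param map NOVA map data frame (default [default_nova_map()]).
#' @return Character vector of classes among MPF, PF, UPF.
#' @examples
#' classify_food("bread")    # PF
#' classify_food("yogurt")   # UPF
#' @export
classify_food <- function(food, map = default_nova_map()) {
  idx <- match(food, map$food)
  if (anyNA(idx))
    stop("food label(s) not in the vocabulary: ",
         paste(unique(food[is.na(idx)]), collapse = ", "))
  map$class[idx]
}

.check_records <- function(records, map = default_nova_map()) {
  need <- c("child_id", "occasion", "food")
  if (!all(need %in% names(records)))
    stop("food records need columns ", paste(need, collapse = ", "))
  bad_occ <- setdiff(unique(records$occasion), eating_occasions())
  if (length(bad_occ))
    stop("unknown eating occasion(s): ", paste(bad_occ, collapse = ", "))
  bad_food <- setdiff(unique(records$food), map$food)
  if (length(bad_food))
    stop("food label(s) not in the vocabulary: ",
         paste(bad_food, collapse = ", "))
  invisible(records)
}

#' Read food-recall records from a long-format CSV
#'
#' @param path CSV with header `child_id,occasion,food`, one row per reported
#'   food per eating occasion.
#' @param map NOVA map used to validate the food vocabulary.
#' @return Data frame of validated records.
#' @export
read_food_records <- function(path, map = default_nova_map()) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(child_id = "character"))
  .check_records(rec, map)
  rec
}

#' Remove children with implausible recall reports
#'
#' Two exclusion rules, applied in order to the per-child daily food-item
#' counts: (1) children reporting fewer than `min_items` foods are removed;
#' (2) among the remaining children, those whose count exceeds
#' `mean + sd_multiplier * SD` of the remaining counts are removed.
#'
#' @param records food-record data frame (`child_id`, `occasion`, `food`).
#' @param sd_multiplier multiplier of the count SD for the outlier rule
#'   (default 3).
#' @param min_items minimum plausible daily food count (default 4).
#' @return List with `records` (the kept rows) and `log`, a data frame of
#'   excluded children (`child_id`, `n_foods`, `rule`).
#' @export
clean_reports <- function(records, sd_multiplier = 3, min_items = 4) {
  empty_log <- data.frame(child_id = character(), n_foods = integer(),
                          rule = character(), stringsAsFactors = FALSE)
  if (nrow(records) == 0L)
    return(list(records = records, log = empty_log))
  counts <- table(records$child_id)
  low <- names(counts)[counts < min_items]
  keep <- counts[!(names(counts) %in% low)]
  if (length(keep)) {
    mu <- mean(keep); sdv <- stats::sd(as.numeric(keep))
    if (is.na(sdv)) sdv <- 0
    high <- names(keep)[keep > mu + sd_multiplier * sdv]
  } else high <- character()
  log <- rbind(
    data.frame(child_id = low, n_foods = as.integer(counts[low]),
               rule = rep("fewer_than_min_items", length(low)),
               stringsAsFactors = FALSE),
    data.frame(child_id = high, n_foods = as.integer(counts[high]),
               rule = rep("count_above_mean_plus_sd", length(high)),
               stringsAsFactors = FALSE))
  drop <- c(low, high)
  list(records = records[!(records$child_id %in% drop), , drop = FALSE],
       log = if (nrow(log)) log else empty_log)
}

#' Build the 18 binary consumption items from food records
#'
#' A child scores 1 on item "class g at occasion m" if they reported at least
#' one food of NOVA class g at occasion m, and 0 otherwise; an occasion with
#' no reported foods contributes 0 to all three of its items. The result is
#' invariant to row order and to duplicated food rows.
#'
#' @param records food-record data frame (ideally after [clean_reports()]).
#' @param map NOVA map (default [default_nova_map()]).
#' @return Integer 0/1 matrix, children x 18 items (`i01`..`i18`), children in
#'   first-appearance order.
#' @export
build_items <- function(records, map = default_nova_map()) {
  .check_records(records, map)
  layout <- mesa_item_layout()
  children <- unique(records$child_id)
  mat <- matrix(0L, length(children), nrow(layout),
                dimnames = list(children, layout$item))
  if (nrow(records)) {
    cls <- classify_food(records$food, map)
    col <- match(paste(records$occasion, cls),
                 paste(layout$occasion, layout$class))
    row <- match(records$child_id, children)
    mat[cbind(row, col)] <- 1L
  }
  mat
}

#' Subset response-matrix columns to a retained item set
#'
#' @param responses binary response matrix with item column names.
#' @param keep character vector of item labels to retain; the output columns
#'   follow the order of `keep` (e.g. the published retained-scale order).
#' @return The column-subset matrix.
#' @export
subset_items <- function(responses, keep) {
  if (length(keep) == 0L) stop("keep must name at least one item")
  missing <- setdiff(keep, colnames(responses))
  if (length(missing))
    stop("unknown item label(s): ", paste(missing, collapse = ", "))
  responses[, keep, drop = FALSE]
}

#' Write / read a binary response matrix as wide CSV
#'
#' @param responses binary matrix with child ids as row names.
#' @param path CSV path (`child_id` column followed by the item columns).
#' @return `write_response_matrix` returns `path` invisibly;
#'   `read_response_matrix` returns the integer matrix.
#' @export
write_response_matrix <- function(responses, path) {
  df <- data.frame(child_id = rownames(responses), responses,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = c(child_id = "character"))
  mat <- as.matrix(df[, setdiff(names(df), "child_id"), drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$child_id
  mat
}
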