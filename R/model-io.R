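#' Write / read a GGUM model as JSON
#'
#' Serializes a [ggum_model()] to a JSON document holding the item parameter
#' sets, the trait reference distribution, the reporting transformation and
#' the level cut-offs. Numbers are written with 15 significant digits so a
#' write/read round trip reproduces the model bit-for-bit at that precision.
#'
#' @param model a [ggum_model()].
#' @param path file path to write to / read from.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns a `ggum_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "ggum_model"))
  doc <- list(
    items = lapply(model$items, function(it)
      list(id = it$item_id, alpha = it$alpha, delta = it$delta,
           tau = as.list(it$tau))),
    trait = list(mean = model$trait_mean, sd = model$trait_sd),
    transformation = list(mean = unname(model$transformation["mean"]),
                          sd = unname(model$transformation["sd"])),
    levels = list(lower = unname(model$level_cutoffs["lower"]),
                  upper = unname(model$level_cutoffs["upper"])))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(15), pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  items <- lapply(doc$items, function(it)
    ggum_item(it$id, as.numeric(it$alpha), as.numeric(it$delta),
              as.numeric(unlist(it$tau))))
  ggum_model(items,
             trait_mean = as.numeric(doc$trait$mean),
             trait_sd = as.numeric(doc$trait$sd),
             transformation = c(mean = as.numeric(doc$transformation$mean),
                                sd = as.numeric(doc$transformation$sd)),
             level_cutoffs = c(lower = as.numeric(doc$levels$lower),
                               upper = as.numeric(doc$levels$upper)))
}
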