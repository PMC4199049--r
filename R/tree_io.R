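## JSON serialisation of fitted trees: split rules, class counts and
## case proportions, round-trippable for prediction.

node_to_list <- function(node) {
  out <- list(n = node$n, w = node$w, w1 = node$w1, w2 = node$w2,
              p1 = node$p1, label = node$label, risk = node$risk)
  if (!is.null(node$split)) {
    s <- node$split
    out$split <- list(var = s$var, type = s$type,
                      threshold = s$threshold,
                      levels_left = as.list(s$levels_left),
                      known_levels = as.list(s$known_levels),
                      missing_left = s$missing_left)
    out$left <- node_to_list(node$left)
    out$right <- node_to_list(node$right)
  }
  out
}

node_from_list <- function(lst) {
  node <- list(n = lst$n, w = lst$w, w1 = lst$w1, w2 = lst$w2,
               p1 = lst$p1, label = lst$label, risk = lst$risk,
               split = NULL, left = NULL, right = NULL)
  if (!is.null(lst$split)) {
    node$split <- list(var = lst$split$var, type = lst$split$type,
                       threshold = if (is.null(lst$split$threshold))
                         NA_real_ else lst$split$threshold,
                       levels_left = unlist(lst$split$levels_left),
                       known_levels = unlist(lst$split$known_levels),
                       missing_left = lst$split$missing_left)
    node$left <- node_from_list(lst$left)
    node$right <- node_from_list(lst$right)
  }
  node
}

#' Serialise a fitted tree to JSON
#'
#' Writes the split rules, per-node class weights and case proportions.
#' The round trip via [tree_from_json()] predicts identically.
#'
#' @param object A fitted [cart()] tree.
#' @param path Optional file path; when `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
tree_to_json <- function(object, path = NULL) {
  stopifnot(inherits(object, "cart"))
  payload <- list(vars = as.list(object$vars),
                  cp = object$cp, minsplit = object$minsplit,
                  minbucket = object$minbucket, n = object$n,
                  root_risk = object$root_risk,
                  prevalence = object$prevalence,
                  root = node_to_list(object$root))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname tree_to_json
#' @param json A path to a JSON file written by [tree_to_json()], or the
#'   JSON string itself.
#' @export
tree_from_json <- function(json) {
  txt <- if (file.exists(json)) paste(readLines(json, warn = FALSE),
                                      collapse = "\n") else json
  lst <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  structure(list(root = node_from_list(lst$root),
                 call = quote(tree_from_json()),
                 vars = unlist(lst$vars), response = "outcome",
                 cp = lst$cp, minsplit = lst$minsplit,
                 minbucket = lst$minbucket, maxdepth = Inf,
                 root_risk = lst$root_risk, n = lst$n,
                 prevalence = lst$prevalence, y = NULL, w = NULL,
                 fitted = NULL),
            class = "cart")
}
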