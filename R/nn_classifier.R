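# Nearest-neighbour screening: a query molecule is predicted active or
# inactive according to the class of its minimum-GED reference molecule.
# Equidistant references are resolved deterministically in favour of the
# lowest input index, so every run is reproducible.

#' Classify one molecule by its nearest reference
#'
#' @param query An `erg_graph`.
#' @param references Non-empty list of `erg_graph` objects with `class` set;
#'   the query must not be among them (by id).
#' @param costs A `cost_table`.
#' @param method `"bipartite"` (default) or `"exact"`.
#' @return A one-row data frame: `query_id`, `predicted`, `neighbor_id`,
#'   `distance`.
#' @export
classify_nn <- function(query, references, costs,
                        method = c("bipartite", "exact")) {
  method <- match.arg(method)
  if (length(references) == 0L)
    stop("references must be non-empty", call. = FALSE)
  ref_ids <- vapply(references, function(g) g$id, character(1))
  if (query$id %in% ref_ids)
    stop("query '", query$id, "' is among the references", call. = FALSE)
  d <- vapply(references, function(r) ged(query, r, costs, method)$distance,
              numeric(1))
  k <- which.min(d)  # lowest index on ties
  data.frame(query_id = query$id,
             predicted = references[[k]]$class,
             neighbor_id = references[[k]]$id,
             distance = d[k],
             stringsAsFactors = FALSE)
}

#' Nearest-neighbour classification accuracy
#'
#' Classifies every test molecule against the references and reports the
#' percentage predicted in its true class.
#'
#' @param test Non-empty list of classed `erg_graph` objects.
#' @param references Non-empty list of classed `erg_graph` objects covering
#'   both classes.
#' @inheritParams classify_nn
#' @param details Return the per-query prediction table as the
#'   `"predictions"` attribute? Default `FALSE`.
#' @return Accuracy in percent (0–100).
#' @export
evaluate_accuracy <- function(test, references, costs,
                              method = c("bipartite", "exact"),
                              details = FALSE) {
  method <- match.arg(method)
  if (length(test) == 0L) stop("test set is empty", call. = FALSE)
  ref_cls <- vapply(references, function(g) g$class, character(1))
  if (length(unique(ref_cls)) < 2L)
    stop("references must contain both classes", call. = FALSE)
  preds <- do.call(rbind, lapply(test, classify_nn, references, costs, method))
  truth <- vapply(test, function(g) g$class, character(1))
  acc <- 100 * mean(preds$predicted == truth)
  if (details) attr(acc, "predictions") <- cbind(preds, truth = truth)
  acc
}
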