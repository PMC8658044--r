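# An edit path is a concrete transformation script between two ErGs: a data
# frame of node and edge operations plus the normaliser L (summed node count
# of the two graphs). Identity substitutions may appear as rows — they record
# the node correspondence — but carry cost 0 and are excluded from the
# operation-kind counts used by the cost-learning update.

#' Construct an edit path
#'
#' @param ops Data frame with columns `entity` (`"node"`/`"edge"`), `op`
#'   (`"sub"`, `"del"`, `"ins"`), `from_label`, `to_label` (NA where not
#'   applicable), `id1`, `id2`. For node operations `id1` is the source-graph
#'   node id and `id2` the target-graph node id; for edge operations `id1`,
#'   `id2` are the endpoint ids (target namespace for substitutions and
#'   insertions, source namespace for deletions). Ids may be NA for
#'   hand-built paths that are only ever costed.
#' @param L Positive integer: `erg_order(ga) + erg_order(gb)`.
#' @return An object of class `edit_path`.
#' @export
edit_path <- function(ops = empty_ops(), L) {
  stopifnot(is.data.frame(ops), is.numeric(L), length(L) == 1L, L >= 0)
  need <- c("entity", "op", "from_label", "to_label", "id1", "id2")
  stopifnot(all(need %in% names(ops)))
  structure(list(ops = ops[need], L = as.integer(L)), class = "edit_path")
}

#' @export
print.edit_path <- function(x, ...) {
  cat(sprintf("edit_path: %d operations, L = %d\n", nrow(x$ops), x$L))
  invisible(x)
}

#' @rdname edit_path
#' @export
empty_ops <- function() {
  data.frame(entity = character(0), op = character(0),
             from_label = character(0), to_label = character(0),
             id1 = character(0), id2 = character(0), stringsAsFactors = FALSE)
}

#' Build one edit-operation row
#'
#' Convenience constructor for the rows of an [edit_path()] operation
#' table, used when assembling an edit script by hand.
#'
#' @param entity `"node"` or `"edge"`.
#' @param op `"sub"`, `"del"` or `"ins"`.
#' @param from_label,to_label Labels before/after (NA where not applicable:
#'   deletions have no `to_label`, insertions no `from_label`).
#' @param id1,id2 Element ids (see [edit_path()]); may be NA for scripts
#'   that are only ever costed, not applied.
#' @return A one-row data frame suitable for `rbind()`ing into an
#'   [edit_path()].
#' @examples
#' edit_path(rbind(op_row("node", "sub", "[7]", "[2]"),
#'                 op_row("edge", "sub", "-", "=")), L = 8)
#' @export
op_row <- function(entity, op, from_label = NA_character_,
                   to_label = NA_character_, id1 = NA_character_,
                   id2 = NA_character_) {
  data.frame(entity = entity, op = op, from_label = from_label,
             to_label = to_label, id1 = id1, id2 = id2,
             stringsAsFactors = FALSE)
}

# kind key of one op row; NA for identity substitutions
op_kind <- function(entity, op, from_label, to_label) {
  if (entity == "node") {
    if (op == "sub") {
      if (identical(from_label, to_label)) return(NA_character_)
      return(kind_node_sub(from_label, to_label))
    }
    return(kind_node_indel(if (op == "del") from_label else to_label))
  }
  if (op == "sub") {
    if (edge_label_index(from_label) == edge_label_index(to_label))
      return(NA_character_)
    return(kind_edge_sub(from_label, to_label))
  }
  kind_edge_indel(if (op == "del") from_label else to_label)
}

#' Tally an edit path by operation kind
#'
#' @param path An `edit_path`.
#' @return Named integer vector of counts over kind keys; identity
#'   substitutions are not counted.
#' @export
path_kind_counts <- function(path) {
  ops <- path$ops
  if (nrow(ops) == 0L) return(stats::setNames(integer(0), character(0)))
  kinds <- vapply(seq_len(nrow(ops)), function(i)
    op_kind(ops$entity[i], ops$op[i], ops$from_label[i], ops$to_label[i]),
    character(1))
  kinds <- kinds[!is.na(kinds)]
  if (length(kinds) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(kinds)
  stats::setNames(as.integer(tab), names(tab))
}

#' Cost of an edit path under a cost table
#'
#' Sums the per-operation penalties \eqn{\sum_t C_t N_t}; identity
#' substitutions cost 0. With `normalize = TRUE` the sum is divided by the
#' path's normaliser `L`, the summed node count of the two graphs.
#'
#' @param path An `edit_path`.
#' @param costs A `cost_table`.
#' @param normalize Divide by `L`? Default `TRUE`.
#' @return Non-negative numeric.
#' @export
edit_path_cost <- function(path, costs, normalize = TRUE) {
  counts <- path_kind_counts(path)
  raw <- 0
  for (k in names(counts)) raw <- raw + cost_of(costs, k) * counts[[k]]
  if (!normalize) return(raw)
  if (path$L == 0L) 0 else raw / path$L
}

#' Apply an edit path to a graph
#'
#' Reconstructs the target graph from the source graph and the script:
#' node substitutions rename `id1` to `id2` and relabel; node deletions drop
#' the node (all incident edges must be covered by edge deletions); node
#' insertions add `id2`; edge operations are matched by endpoint pair.
#' Used to verify that a returned path is a valid transformation.
#'
#' @param g Source `erg_graph`.
#' @param path An `edit_path` with non-NA ids.
#' @return The transformed `erg_graph` (id suffixed `"+edited"`).
#' @export
apply_edit_path <- function(g, path) {
  ops <- path$ops
  nops <- ops[ops$entity == "node", , drop = FALSE]
  eops <- ops[ops$entity == "edge", , drop = FALSE]
  if (anyNA(nops$id1[nops$op != "ins"]) || anyNA(nops$id2[nops$op != "del"]))
    stop("path has NA ids; only fully-identified paths can be applied", call. = FALSE)

  subs <- nops[nops$op == "sub", , drop = FALSE]
  dels <- nops[nops$op == "del", , drop = FALSE]
  ins  <- nops[nops$op == "ins", , drop = FALSE]
  covered <- c(subs$id1, dels$id1)
  if (anyDuplicated(covered))
    stop("a source node appears in more than one node operation", call. = FALSE)
  if (!all(covered %in% names(g$nodes)))
    stop("node operation references a node absent from the source graph", call. = FALSE)
  # nodes without an explicit operation pass through unchanged
  untouched <- setdiff(names(g$nodes), covered)
  rename <- stats::setNames(c(subs$id2, untouched), c(subs$id1, untouched))
  out_nodes <- stats::setNames(
    c(subs$to_label, g$nodes[untouched], ins$to_label),
    c(subs$id2, untouched, ins$id2))

  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edel <- eops[eops$op == "del", , drop = FALSE]
  esub <- eops[eops$op == "sub", , drop = FALSE]
  eins <- eops[eops$op == "ins", , drop = FALSE]
  del_keys <- ekey(edel$id1, edel$id2)
  sub_keys <- ekey(esub$id1, esub$id2)

  ef <- character(0); et <- character(0); el <- character(0)
  if (nrow(g$edges) > 0L) for (i in seq_len(nrow(g$edges))) {
    a <- g$edges$from[i]; b <- g$edges$to[i]; lab <- g$edges$label[i]
    if (ekey(a, b) %in% del_keys) next
    if (!(a %in% names(rename)) || !(b %in% names(rename)))
      stop(sprintf("edge (%s,%s) touches a deleted node but has no deletion op", a, b),
           call. = FALSE)
    na_ <- rename[[a]]; nb_ <- rename[[b]]
    j <- match(ekey(na_, nb_), sub_keys)
    if (!is.na(j)) lab <- esub$to_label[j]
    ef <- c(ef, na_); et <- c(et, nb_); el <- c(el, lab)
  }
  if (nrow(eins) > 0L) {
    ef <- c(ef, eins$id1); et <- c(et, eins$id2); el <- c(el, eins$to_label)
  }
  edges <- if (length(ef) > 0L)
    data.frame(from = ef, to = et, label = el, stringsAsFactors = FALSE)
  else NULL
  erg_graph(paste0(g$id, "+edited"), out_nodes, edges)
}
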