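#' Construct an extended reduced graph
#'
#' An `erg_graph` is a simple undirected attributed graph: each node carries
#' one of the fifteen pharmacophore labels in [erg_node_labels] and each edge
#' one of the three bond labels in [erg_edge_labels]. Node ids are opaque
#' strings local to the graph; Graph Edit Distance never assumes cross-graph
#' id identity.
#'
#' @param id Graph identifier (string).
#' @param nodes Named character vector: names are node ids, values are node
#'   labels. An unnamed vector gets ids `"n1"`, `"n2"`, ...
#' @param edges A data frame with columns `from`, `to`, `label`, or `NULL`
#'   for an edgeless graph. The triple bond may be written `"≡"` or `"#T"`.
#' @param class Optional activity class, `"active"` or `"inactive"`.
#' @return An object of class `erg_graph` with elements `id`, `nodes`
#'   (named label vector), `edges` (data frame `from`, `to`, `label`) and
#'   `class`.
#' @examples
#' g <- erg_graph("mol1", c(a = "[1]", b = "[6]"), data.frame(
#'   from = "a", to = "b", label = "-"))
#' erg_order(g)
#' @export
erg_graph <- function(id, nodes = character(0), edges = NULL, class = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L)
  labels <- as.character(nodes)
  if (is.null(names(nodes)) && length(nodes) > 0L)
    names(labels) <- paste0("n", seq_along(labels))
  else
    names(labels) <- names(nodes)
  if (length(labels) > 0L) assert_node_labels(labels)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        label = character(0), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        label = as.character(edges$label),
                        stringsAsFactors = FALSE)
    assert_edge_labels(edges$label)
    edges$label <- erg_edge_labels[edge_label_index(edges$label)]
  }
  if (!is.na(class) && !class %in% c("active", "inactive"))
    stop("class must be 'active', 'inactive' or NA", call. = FALSE)
  g <- structure(list(id = id, nodes = labels, edges = edges, class = class),
                 class = "erg_graph")
  viol <- validate_graph(g)
  if (length(viol) > 0L) stop(viol[1L], call. = FALSE)
  g
}

#' Number of nodes of an ErG
#' @param g An `erg_graph`.
#' @return Integer node count.
#' @export
erg_order <- function(g) length(g$nodes)

#' @export
print.erg_graph <- function(x, ...) {
  cat(sprintf("erg_graph '%s'%s: %d nodes, %d edges\n", x$id,
              if (is.na(x$class)) "" else paste0(" (", x$class, ")"),
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Validate the structural invariants of an ErG
#'
#' Checks that the graph is simple (no self-loops, at most one edge per
#' unordered node pair), that every edge endpoint is a declared node, and
#' that all labels belong to the closed alphabets.
#'
#' @param g An `erg_graph` (or a list with the same fields).
#' @return Character vector of violation descriptions; empty if valid.
#' @export
validate_graph <- function(g) {
  v <- character(0)
  ids <- names(g$nodes)
  if (anyDuplicated(ids))
    v <- c(v, sprintf("duplicate node id '%s'", ids[duplicated(ids)][1L]))
  bad <- g$nodes[is.na(node_label_index(g$nodes))]
  if (length(bad) > 0L)
    v <- c(v, sprintf("unknown node label '%s'", bad[1L]))
  e <- g$edges
  if (NROW(e) > 0L) {
    loops <- e$from == e$to
    if (any(loops))
      v <- c(v, sprintf("self-loop at node '%s'", e$from[loops][1L]))
    dangling <- !(e$from %in% ids) | !(e$to %in% ids)
    if (any(dangling))
      v <- c(v, sprintf("edge (%s,%s) references an undeclared node",
                        e$from[dangling][1L], e$to[dangling][1L]))
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key))
      v <- c(v, sprintf("duplicate edge between '%s' and '%s'",
                        e$from[duplicated(key)][1L], e$to[duplicated(key)][1L]))
    badl <- e$label[is.na(edge_label_index(e$label))]
    if (length(badl) > 0L)
      v <- c(v, sprintf("unknown edge label '%s'", badl[1L]))
  }
  v
}

# canonical form used for graph equality: sorted node table + sorted edge keys
canonical_erg <- function(g) {
  ids <- names(g$nodes)
  o <- order(ids)
  ekey <- character(0)
  if (nrow(g$edges) > 0L) {
    ekey <- sort(paste(pmin(g$edges$from, g$edges$to),
                       pmax(g$edges$from, g$edges$to), g$edges$label,
                       sep = ""))
  }
  list(nodes = g$nodes[o], edges = ekey)
}

#' Test two ErGs for exact equality up to element order
#'
#' Equality of node id/label pairs and edge sets; the graph `id` and `class`
#' fields are ignored.
#' @param a,b `erg_graph` objects.
#' @return Logical.
#' @export
erg_identical <- function(a, b) {
  identical(canonical_erg(a), canonical_erg(b))
}

#' Read ErG graphs from a native-format file
#'
#' The native format is line-oriented, one or more graphs per file, blank
#' lines between graphs:
#' \preformatted{
#' graph <id> [<class>]
#' n <node-id> <label>
#' e <node-id> <node-id> <label>
#' }
#' Node labels are the bracketed symbols of [erg_node_labels]; edge labels
#' are `-`, `=`, and `≡` (alias `#T`).
#'
#' @param path File path.
#' @return List of `erg_graph` objects, in file order.
#' @export
read_erg_graphs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  graphs <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    edges <- if (length(cur$ef) > 0L)
      data.frame(from = cur$ef, to = cur$et, label = cur$el,
                 stringsAsFactors = FALSE) else NULL
    labs <- cur$nl; names(labs) <- cur$ni
    erg_graph(cur$id, labs, edges, class = cur$class)
  }
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (ln == "") { g <- flush(cur); if (!is.null(g)) graphs <- c(graphs, list(g)); cur <- NULL; next }
    tok <- strsplit(ln, "[ \t]+")[[1]]
    err <- function(msg) stop(sprintf("%s (line %d of %s)", msg, k, path), call. = FALSE)
    if (tok[1] == "graph") {
      if (length(tok) < 2L) err("graph header needs an id")
      g <- flush(cur); if (!is.null(g)) graphs <- c(graphs, list(g))
      cur <- list(id = tok[2],
                  class = if (length(tok) >= 3L) tok[3] else NA_character_,
                  ni = character(0), nl = character(0),
                  ef = character(0), et = character(0), el = character(0))
    } else if (tok[1] == "n") {
      if (is.null(cur)) err("node line before any graph header")
      if (length(tok) != 3L) err("node line needs: n <id> <label>")
      if (is.na(node_label_index(tok[3]))) err(sprintf("unknown node label '%s'", tok[3]))
      cur$ni <- c(cur$ni, tok[2]); cur$nl <- c(cur$nl, tok[3])
    } else if (tok[1] == "e") {
      if (is.null(cur)) err("edge line before any graph header")
      if (length(tok) != 4L) err("edge line needs: e <id1> <id2> <label>")
      if (is.na(edge_label_index(tok[4]))) err(sprintf("unknown edge label '%s'", tok[4]))
      key <- paste(pmin(tok[2], tok[3]), pmax(tok[2], tok[3]))
      old <- paste(pmin(cur$ef, cur$et), pmax(cur$ef, cur$et))
      if (key %in% old) err(sprintf("duplicate edge between '%s' and '%s'", tok[2], tok[3]))
      cur$ef <- c(cur$ef, tok[2]); cur$et <- c(cur$et, tok[3]); cur$el <- c(cur$el, tok[4])
    } else err(sprintf("unrecognised line type '%s'", tok[1]))
  }
  g <- flush(cur); if (!is.null(g)) graphs <- c(graphs, list(g))
  graphs
}

#' Write ErG graphs in the native format
#'
#' Writes the canonical form: nodes in stored order, edges in stored order,
#' triple bonds as the portable `#T` alias. `read_erg_graphs()` followed by
#' `write_erg_graphs()` reproduces a byte-identical canonical file.
#'
#' @param graphs A list of `erg_graph` objects (or a single graph).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_erg_graphs <- function(graphs, path) {
  if (inherits(graphs, "erg_graph")) graphs <- list(graphs)
  out <- character(0)
  for (g in graphs) {
    hdr <- if (is.na(g$class)) paste("graph", g$id) else paste("graph", g$id, g$class)
    lab <- g$edges$label
    lab[lab == erg_edge_labels[3]] <- .triple_alias
    out <- c(out, hdr,
             paste("n", names(g$nodes), g$nodes),
             if (nrow(g$edges) > 0L) paste("e", g$edges$from, g$edges$to, lab),
             "")
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}

#' Assemble a labeled train/test dataset for one screening target
#'
#' @param name Target name (e.g. `"CDK2"`).
#' @param train,test Lists of `erg_graph` objects whose `class` field is set.
#' @return An object of class `erg_dataset`.
#' @export
erg_dataset <- function(name, train, test) {
  chk <- function(lst, half) {
    cls <- vapply(lst, function(g) g$class, character(1))
    if (anyNA(cls))
      stop(half, " contains graphs without a class label", call. = FALSE)
    cls
  }
  ctr <- chk(train, "train"); cte <- chk(test, "test")
  idtr <- vapply(train, function(g) g$id, character(1))
  idte <- vapply(test, function(g) g$id, character(1))
  if (length(intersect(idtr, idte)) > 0L)
    stop("train and test share graph ids: ", intersect(idtr, idte)[1L], call. = FALSE)
  if (length(unique(ctr)) < 2L)
    stop("train must contain both classes", call. = FALSE)
  structure(list(name = name, train = train, test = test),
            class = "erg_dataset")
}

#' @export
print.erg_dataset <- function(x, ...) {
  cat(sprintf("erg_dataset '%s': %d train / %d test molecules\n",
              x$name, length(x$train), length(x$test)))
  invisible(x)
}

#' Read a two-column graph-id/half split file
#'
#' @param path Tab-separated file with columns graph-id and `train`/`test`.
#' @return Named character vector mapping graph id to half.
#' @export
read_split <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("id", "half"))
  if (!all(df$half %in% c("train", "test")))
    stop("split file halves must be 'train' or 'test'", call. = FALSE)
  stats::setNames(df$half, df$id)
}
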