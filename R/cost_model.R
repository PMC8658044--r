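# The edit-cost model has exactly C(15,2) + 15 + C(3,2) + 3 = 126 learnable
# parameters: unordered node-substitution pairs, one tied insert/delete cost
# per node label, unordered edge-substitution pairs, and one tied
# insert/delete cost per edge label. Identity substitutions are structurally
# fixed at 0 and are not parameters.

#' Construct an edit-cost table
#'
#' @param node_sub 15x15 symmetric numeric matrix of node substitution costs
#'   (rows/columns in [erg_node_labels] order, zero diagonal).
#' @param node_indel Numeric vector of 15 tied insertion/deletion costs.
#' @param edge_sub 3x3 symmetric matrix of edge substitution costs.
#' @param edge_indel Numeric vector of 3 tied edge insertion/deletion costs.
#' @param provenance String tag recording where the values came from.
#' @return An object of class `cost_table`.
#' @export
cost_table <- function(node_sub, node_indel, edge_sub, edge_indel,
                       provenance = "custom") {
  node_sub <- as.matrix(node_sub); edge_sub <- as.matrix(edge_sub)
  node_indel <- as.numeric(node_indel); edge_indel <- as.numeric(edge_indel)
  stopifnot(all(dim(node_sub) == c(15L, 15L)),
            length(node_indel) == 15L,
            all(dim(edge_sub) == c(3L, 3L)),
            length(edge_indel) == 3L)
  dimnames(node_sub) <- list(erg_node_labels, erg_node_labels)
  dimnames(edge_sub) <- list(erg_edge_labels, erg_edge_labels)
  names(node_indel) <- erg_node_labels
  names(edge_indel) <- erg_edge_labels
  ct <- structure(list(node_sub = node_sub, node_indel = node_indel,
                       edge_sub = edge_sub, edge_indel = edge_indel,
                       provenance = provenance),
                  class = "cost_table")
  viol <- validate_cost_table(ct)
  if (length(viol) > 0L) stop(viol[1L], call. = FALSE)
  ct
}

#' Validate a cost table
#'
#' Checks completeness (no missing values), non-negativity, symmetry of both
#' substitution matrices and exact-zero diagonals. Insert/delete tying is
#' structural (a single stored parameter per label).
#'
#' @param ct A `cost_table`.
#' @return Character vector of violations; empty if valid.
#' @export
validate_cost_table <- function(ct) {
  v <- character(0)
  vals <- c(ct$node_sub, ct$node_indel, ct$edge_sub, ct$edge_indel)
  if (anyNA(vals)) v <- c(v, "cost table contains missing values")
  else if (any(vals < 0)) v <- c(v, "cost table contains negative values")
  if (!isTRUE(all.equal(ct$node_sub, t(ct$node_sub), tolerance = 0)))
    v <- c(v, "node substitution matrix is not symmetric")
  if (!isTRUE(all.equal(ct$edge_sub, t(ct$edge_sub), tolerance = 0)))
    v <- c(v, "edge substitution matrix is not symmetric")
  if (any(diag(ct$node_sub) != 0) || any(diag(ct$edge_sub) != 0))
    v <- c(v, "identity substitution costs must be exactly 0")
  v
}

#' @export
print.cost_table <- function(x, ...) {
  cat(sprintf("cost_table (%s): %d parameters\n", x$provenance,
              n_cost_parameters(x)))
  invisible(x)
}

#' Number of learnable edit-cost parameters
#'
#' Counted from the stored structures: strictly-upper-triangular entries of
#' both substitution matrices plus one tied insert/delete parameter per
#' label. For the ErG alphabets this is 105 + 15 + 3 + 3 = 126.
#'
#' @param ct A `cost_table`.
#' @return Integer.
#' @export
n_cost_parameters <- function(ct) {
  n <- nrow(ct$node_sub); e <- nrow(ct$edge_sub)
  as.integer(n * (n - 1) / 2 + length(ct$node_indel) +
             e * (e - 1) / 2 + length(ct$edge_indel))
}

#' Harper expert default edit costs
#'
#' The node and edge substitution, insertion and deletion penalties proposed
#' by Harper and colleagues for comparing extended reduced graphs: related
#' pharmacophore features (e.g. donor vs donor+acceptor) substitute for 1,
#' unrelated ones for 2, anything involving the non-carbon link node for 3;
#' link nodes are cheap to insert (1), feature nodes cost 2; single bonds
#' insert for free, higher bond orders for 1; any bond-order change costs 3.
#'
#' @return A `cost_table` with provenance `"harper"`.
#' @export
harper_costs <- function() {
  ns <- matrix(c(
    0, 2, 2, 2, 2, 2, 2, 3, 1, 1, 1, 2, 2, 2, 1,
    2, 0, 2, 2, 2, 2, 2, 3, 1, 2, 2, 1, 1, 2, 1,
    2, 2, 0, 2, 2, 2, 2, 3, 2, 1, 2, 1, 2, 1, 1,
    2, 2, 2, 0, 2, 2, 2, 3, 2, 2, 1, 2, 1, 1, 2,
    2, 2, 2, 2, 0, 2, 2, 3, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 0, 2, 3, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 0, 3, 2, 2, 2, 2, 2, 2, 2,
    3, 3, 3, 3, 3, 3, 3, 0, 3, 3, 3, 3, 3, 3, 3,
    1, 1, 2, 2, 2, 2, 2, 3, 0, 2, 2, 2, 2, 2, 2,
    1, 2, 1, 2, 2, 2, 2, 3, 2, 0, 2, 2, 2, 2, 2,
    1, 2, 2, 1, 2, 2, 2, 3, 2, 2, 0, 2, 2, 2, 2,
    2, 1, 1, 2, 2, 2, 2, 3, 2, 2, 2, 0, 2, 2, 2,
    2, 1, 2, 1, 2, 2, 2, 3, 2, 2, 2, 2, 0, 2, 2,
    2, 2, 1, 1, 2, 2, 2, 3, 2, 2, 2, 2, 2, 0, 2,
    1, 1, 1, 2, 2, 2, 2, 3, 2, 2, 2, 2, 2, 2, 0),
    nrow = 15L, byrow = TRUE)
  ni <- c(2, 2, 2, 2, 2, 2, 1, 1, 2, 2, 2, 2, 2, 2, 2)
  es <- matrix(c(0, 3, 3,  3, 0, 3,  3, 3, 0), nrow = 3L, byrow = TRUE)
  ei <- c(0, 1, 1)
  cost_table(ns, ni, es, ei, provenance = "harper")
}

#' Published learned edit costs
#'
#' The cost table obtained by the iterative learning algorithm when trained
#' on the six public screening benchmarks and averaged across them (50
#' iterations, Harper initialisation). Shipped as reported, to two decimals,
#' for user convenience; these values depend on the external benchmark data
#' and are not reproduced by this package's test suite.
#'
#' @return A `cost_table` with provenance `"learned"`.
#' @export
learned_costs <- function() {
  ns <- matrix(c(
    0.00, 1.99, 2.02, 2.00, 1.99, 2.04, 2.05, 3.00, 1.06, 0.99, 1.00, 2.00, 2.00, 2.00, 0.97,
    1.99, 0.00, 2.00, 2.00, 1.98, 1.99, 1.96, 3.00, 1.02, 1.99, 2.00, 1.02, 1.00, 2.00, 1.04,
    2.02, 2.00, 0.00, 2.00, 2.00, 2.00, 1.99, 3.00, 2.00, 0.99, 2.00, 1.00, 2.00, 1.00, 0.98,
    2.00, 2.00, 2.00, 0.00, 2.00, 2.00, 2.05, 3.00, 1.99, 2.00, 1.00, 2.00, 1.00, 1.00, 2.00,
    1.99, 1.98, 2.00, 2.00, 0.00, 1.99, 2.01, 3.00, 2.01, 2.01, 2.00, 2.00, 2.00, 2.00, 2.00,
    2.04, 1.99, 2.00, 2.00, 1.99, 0.00, 1.99, 3.00, 1.96, 1.96, 2.00, 2.00, 2.00, 2.00, 2.02,
    2.05, 1.96, 1.99, 2.05, 2.01, 1.99, 0.00, 3.00, 2.00, 2.01, 2.00, 2.00, 2.00, 2.00, 1.98,
    3.00, 3.00, 3.00, 3.00, 3.00, 3.00, 3.00, 0.00, 3.00, 3.00, 3.00, 3.00, 3.00, 3.00, 3.00,
    1.06, 1.02, 2.00, 1.99, 2.01, 1.96, 2.00, 3.00, 0.00, 2.02, 2.00, 2.00, 2.00, 2.00, 2.01,
    0.99, 1.99, 0.99, 2.00, 2.01, 1.96, 2.01, 3.00, 2.02, 0.00, 2.00, 2.00, 2.00, 2.00, 2.00,
    1.00, 2.00, 2.00, 1.00, 2.00, 2.00, 2.00, 3.00, 2.00, 2.00, 0.00, 2.00, 2.00, 2.00, 2.00,
    2.00, 1.02, 1.00, 2.00, 2.00, 2.00, 2.00, 3.00, 2.00, 2.00, 2.00, 0.00, 2.00, 2.00, 2.00,
    2.00, 1.00, 2.00, 1.00, 2.00, 2.00, 2.00, 3.00, 2.00, 2.00, 2.00, 2.00, 0.00, 2.00, 2.00,
    2.00, 2.00, 1.00, 1.00, 2.00, 2.00, 2.00, 3.00, 2.00, 2.00, 2.00, 2.00, 2.00, 0.00, 2.00,
    0.97, 1.04, 0.98, 2.00, 2.00, 2.02, 1.98, 3.00, 2.01, 2.00, 2.00, 2.00, 2.00, 2.00, 0.00),
    nrow = 15L, byrow = TRUE)
  ni <- c(1.95, 1.98, 2.00, 2.00, 1.99, 1.89, 0.97, 1.00,
          2.03, 2.02, 2.00, 1.99, 2.00, 2.00, 1.96)
  es <- matrix(c(0, 3, 3,  3, 0, 3,  3, 3, 0), nrow = 3L, byrow = TRUE)
  ei <- c(0, 1.02, 1.00)
  cost_table(ns, ni, es, ei, provenance = "learned")
}

#' Uniform edit costs
#'
#' All 126 parameters set to the same value. `uniform_costs(1)` is the
#' "all ones" initialisation; `uniform_costs(0)` makes every distance zero.
#'
#' @param value Non-negative scalar.
#' @return A `cost_table`; provenance `"ones"` when `value == 1`.
#' @export
uniform_costs <- function(value = 1) {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  ns <- matrix(value, 15L, 15L); diag(ns) <- 0
  es <- matrix(value, 3L, 3L); diag(es) <- 0
  cost_table(ns, rep(value, 15L), es, rep(value, 3L),
             provenance = if (value == 1) "ones" else sprintf("uniform(%g)", value))
}

#' Parameter-wise mean of cost tables
#'
#' @param tables Non-empty list of `cost_table` objects.
#' @return A `cost_table` with provenance `"mean"`.
#' @export
mean_costs <- function(tables) {
  if (!is.list(tables) || length(tables) == 0L ||
      !all(vapply(tables, inherits, logical(1), "cost_table")))
    stop("'tables' must be a non-empty list of cost_table objects", call. = FALSE)
  k <- length(tables)
  cost_table(
    Reduce(`+`, lapply(tables, `[[`, "node_sub")) / k,
    Reduce(`+`, lapply(tables, `[[`, "node_indel")) / k,
    Reduce(`+`, lapply(tables, `[[`, "edge_sub")) / k,
    Reduce(`+`, lapply(tables, `[[`, "edge_indel")) / k,
    provenance = "mean")
}

# --- kind-key access --------------------------------------------------------

# split "ns:[0]|[7]" -> c("ns", "[0]", "[7]"); indel keys have length 2
split_kind <- function(key) {
  pre <- substr(key, 1L, 2L)
  rest <- substring(key, 4L)
  c(pre, strsplit(rest, "|", fixed = TRUE)[[1]])
}

#' Look up the cost of one edit-operation kind
#'
#' @param ct A `cost_table`.
#' @param key Kind key as produced by `kind_node_sub()`, `kind_node_indel()`,
#'   `kind_edge_sub()` or `kind_edge_indel()`.
#' @return Numeric cost.
#' @export
cost_of <- function(ct, key) {
  p <- split_kind(key)
  switch(p[1],
         ns = ct$node_sub[p[2], p[3]],
         ni = ct$node_indel[[p[2]]],
         es = ct$edge_sub[p[2], p[3]],
         ei = ct$edge_indel[[p[2]]],
         stop("unknown kind key: ", key, call. = FALSE))
}

# set one parameter, preserving symmetry / insert-delete tying
set_cost <- function(ct, key, value) {
  p <- split_kind(key)
  switch(p[1],
         ns = { ct$node_sub[p[2], p[3]] <- value; ct$node_sub[p[3], p[2]] <- value },
         ni = ct$node_indel[[p[2]]] <- value,
         es = { ct$edge_sub[p[2], p[3]] <- value; ct$edge_sub[p[3], p[2]] <- value },
         ei = ct$edge_indel[[p[2]]] <- value,
         stop("unknown kind key: ", key, call. = FALSE))
  ct
}

# --- serialization ----------------------------------------------------------

#' Write a cost table to CSV
#'
#' Flat tabular text, one row per parameter:
#' `kind,label1,label2,value` with `kind` in `node_sub`, `node_indel`,
#' `edge_sub`, `edge_indel` and `label2` empty for insert/delete rows.
#' All 126 values at full precision, deterministic row order.
#'
#' @param ct A `cost_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cost_table <- function(ct, path) {
  keys <- all_kind_keys()
  rows <- lapply(keys, function(k) {
    p <- split_kind(k)
    data.frame(kind = switch(p[1], ns = "node_sub", ni = "node_indel",
                             es = "edge_sub", ei = "edge_indel"),
               label1 = p[2],
               label2 = if (length(p) == 3L) p[3] else "",
               value = cost_of(ct, k),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$label1[df$label1 == erg_edge_labels[3]] <- .triple_alias
  df$label2[df$label2 == erg_edge_labels[3]] <- .triple_alias
  df$value <- format(df$value, digits = 17, scientific = FALSE, trim = TRUE)
  # composite node labels contain commas; quote the label columns
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = c(2L, 3L),
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cost table from CSV
#'
#' Inverse of [write_cost_table()]. The file must define every one of the
#' 126 parameters exactly once with a non-negative value.
#'
#' @param path Input path.
#' @param provenance Provenance tag for the resulting table.
#' @return A `cost_table`.
#' @export
read_cost_table <- function(path, provenance = "file") {
  df <- utils::read.table(path, sep = ",", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  if (!all(c("kind", "label1", "label2", "value") %in% names(df)))
    stop("cost-table file must have columns kind,label1,label2,value", call. = FALSE)
  df$value <- as.numeric(df$value)
  if (anyNA(df$value)) stop("non-numeric cost value in ", path, call. = FALSE)
  if (any(df$value < 0)) {
    i <- which(df$value < 0)[1L]
    stop(sprintf("negative cost for %s %s %s", df$kind[i], df$label1[i], df$label2[i]),
         call. = FALSE)
  }
  key_of_row <- function(kind, l1, l2) {
    switch(kind,
           node_sub = kind_node_sub(l1, l2),
           node_indel = kind_node_indel(l1),
           edge_sub = kind_edge_sub(l1, l2),
           edge_indel = kind_edge_indel(l1),
           stop("unknown kind '", kind, "' in ", path, call. = FALSE))
  }
  keys <- mapply(key_of_row, df$kind, df$label1, df$label2)
  if (anyDuplicated(keys))
    stop("duplicate parameter in ", path, ": ", keys[duplicated(keys)][1L], call. = FALSE)
  missing <- setdiff(all_kind_keys(), keys)
  if (length(missing) > 0L)
    stop("missing parameter in ", path, ": ", missing[1L], call. = FALSE)
  ct <- uniform_costs(0)
  for (i in seq_along(keys)) ct <- set_cost(ct, keys[i], df$value[i])
  ct$provenance <- provenance
  viol <- validate_cost_table(ct)
  if (length(viol) > 0L) stop(viol[1L], call. = FALSE)
  ct
}
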