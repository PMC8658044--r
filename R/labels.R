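#' Pharmacophore node alphabet of an extended reduced graph
#'
#' The fifteen node attributes an ErG node may carry: hydrogen-bond donor
#' `[0]`, hydrogen-bond acceptor `[1]`, positive charge `[2]`, negative
#' charge `[3]`, hydrophobic group `[4]`, aromatic ring system `[5]`,
#' carbon link node `[6]`, non-carbon link node `[7]`, and the composite
#' features `[0,1]`, `[0,2]`, `[0,3]`, `[1,2]`, `[1,3]`, `[2,3]` and
#' `[0,1,2]`. Composite labels are atomic symbols: `[0,1]` is a distinct
#' feature, not the set \{donor, acceptor\}, and any similarity between it
#' and `[0]` is expressed exclusively through the edit-cost table.
#'
#' @format Character vector of length 15 in canonical order.
#' @export
erg_node_labels <- c(
  "[0]", "[1]", "[2]", "[3]", "[4]", "[5]", "[6]", "[7]",
  "[0,1]", "[0,2]", "[0,3]", "[1,2]", "[1,3]", "[2,3]", "[0,1,2]"
)

#' Bond edge alphabet of an extended reduced graph
#'
#' The three bond labels: single `-`, double `=` and triple `≡`.
#' In the native file format the triple bond may also be written `#T`.
#'
#' @format Character vector of length 3 in canonical order.
#' @export
erg_edge_labels <- c("-", "=", "\u2261")

# file alias for the triple bond (portability outside UTF-8 terminals)
.triple_alias <- "#T"

# map a user-supplied node label to its canonical index, NA if unknown
node_label_index <- function(label) match(label, erg_node_labels)

edge_label_index <- function(label) {
  label[label == .triple_alias] <- erg_edge_labels[3L]
  match(label, erg_edge_labels)
}

assert_node_labels <- function(labels, where = "node label") {
  bad <- labels[is.na(node_label_index(labels))]
  if (length(bad) > 0L)
    stop(sprintf("unknown %s: '%s'", where, bad[1L]), call. = FALSE)
  invisible(labels)
}

assert_edge_labels <- function(labels, where = "edge label") {
  bad <- labels[is.na(edge_label_index(labels))]
  if (length(bad) > 0L)
    stop(sprintf("unknown %s: '%s'", where, bad[1L]), call. = FALSE)
  invisible(labels)
}

# --- edit-operation kind keys -----------------------------------------------
#
# Every learnable edit-cost parameter is addressed by a canonical string key:
#   "ns:<a>|<b>"  node substitution, a before b in canonical label order
#   "ni:<a>"      node insertion/deletion (one tied parameter)
#   "es:<a>|<b>"  edge substitution
#   "ei:<a>"      edge insertion/deletion
# Identity substitutions are fixed at cost 0 and have no key.

kind_node_sub <- function(a, b) {
  ia <- node_label_index(a); ib <- node_label_index(b)
  stopifnot(!is.na(ia), !is.na(ib), ia != ib)
  if (ia > ib) { tmp <- a; a <- b; b <- tmp }
  paste0("ns:", a, "|", b)
}

kind_node_indel <- function(a) {
  stopifnot(!is.na(node_label_index(a)))
  paste0("ni:", a)
}

kind_edge_sub <- function(a, b) {
  ia <- edge_label_index(a); ib <- edge_label_index(b)
  stopifnot(!is.na(ia), !is.na(ib), ia != ib)
  canon <- erg_edge_labels
  if (ia > ib) paste0("es:", canon[ib], "|", canon[ia])
  else paste0("es:", canon[ia], "|", canon[ib])
}

kind_edge_indel <- function(a) {
  ia <- edge_label_index(a)
  stopifnot(!is.na(ia))
  paste0("ei:", erg_edge_labels[ia])
}

# all 126 parameter keys in deterministic order
all_kind_keys <- function() {
  nl <- erg_node_labels; el <- erg_edge_labels
  ns <- character(0)
  for (i in seq_len(14L)) for (j in (i + 1L):15L)
    ns <- c(ns, paste0("ns:", nl[i], "|", nl[j]))
  es <- c(paste0("es:", el[1], "|", el[2]),
          paste0("es:", el[1], "|", el[3]),
          paste0("es:", el[2], "|", el[3]))
  c(ns, paste0("ni:", nl), es, paste0("ei:", el))
}
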