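# Shared fixtures and the independent brute-force GED oracle.

# The published worked transformation example, hand-transcribed:
# G1 is the 4-node path [1]-[6]-[5]-[7] (all single bonds).
fig2_g1 <- function() {
  erg_graph("G1", c(v1 = "[1]", v2 = "[6]", v3 = "[5]", v4 = "[7]"),
            data.frame(from = c("v1", "v2", "v3"), to = c("v2", "v3", "v4"),
                       label = "-"))
}

# G2 results from the six printed operations: delete node [1] and its single
# bond, insert a node [5] with a single bond, substitute [7] by [2], and
# substitute one single bond by a double bond.
fig2_g2 <- function() {
  erg_graph("G2", c(w0 = "[5]", w2 = "[6]", w3 = "[5]", w4 = "[2]"),
            data.frame(from = c("w0", "w2", "w3"), to = c("w2", "w3", "w4"),
                       label = c("-", "-", "=")))
}

# the six-operation transformation script itself (ids resolve G1 -> G2)
fig2_path <- function() {
  ops <- rbind(
    op_row("edge", "del", from_label = "-", id1 = "v1", id2 = "v2"),
    op_row("node", "del", from_label = "[1]", id1 = "v1"),
    op_row("node", "ins", to_label = "[5]", id2 = "w0"),
    op_row("edge", "ins", to_label = "-", id1 = "w0", id2 = "w2"),
    op_row("node", "sub", "[7]", "[2]", "v4", "w4"),
    op_row("edge", "sub", "-", "=", "w3", "w4"),
    # identity correspondences for the surviving nodes/edges (cost 0)
    op_row("node", "sub", "[6]", "[6]", "v2", "w2"),
    op_row("node", "sub", "[5]", "[5]", "v3", "w3"),
    op_row("edge", "sub", "-", "-", "w2", "w3"))
  edit_path(ops, L = 8L)
}

# internal helpers reached through the installed namespace
mapping_to_path <- ergged:::mapping_to_path

# --- independent oracle: exhaustive enumeration of node mappings -----------
# Costs every injective (partial) mapping via the path builder and the path
# costing function — a different code path from the branch-and-bound's
# incremental accounting.
all_mappings <- function(n1, n2) {
  res <- list()
  rec <- function(i, map, used) {
    if (i > n1) { res[[length(res) + 1L]] <<- map; return(invisible()) }
    for (j in c(which(!used), 0L)) {
      map[i] <- j
      if (j > 0L) used[j] <- TRUE
      rec(i + 1L, map, used)
      if (j > 0L) used[j] <- FALSE
    }
  }
  rec(1L, integer(n1), logical(max(n2, 1L)))
  res
}

brute_force_ged <- function(ga, gb, costs) {
  n1 <- erg_order(ga); n2 <- erg_order(gb)
  best <- Inf
  for (map in all_mappings(n1, n2)) {
    p <- mapping_to_path(ga, gb, map)
    best <- min(best, edit_path_cost(p, costs, normalize = TRUE))
  }
  if (is.infinite(best)) 0 else best
}

# tiny labelled graphs used across tests
path_graph <- function(id, labels, elabels = rep("-", length(labels) - 1L),
                       class = NA_character_) {
  n <- length(labels)
  ids <- paste0("x", seq_len(n))
  labs <- stats::setNames(labels, ids)
  edges <- if (n > 1L)
    data.frame(from = ids[-n], to = ids[-1L], label = elabels,
               stringsAsFactors = FALSE) else NULL
  erg_graph(id, labs, edges, class = class)
}
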