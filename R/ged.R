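# Graph Edit Distance engines.
#
# Both engines work on a compact integer representation of an ErG and return
# a `ged_result`: the normalised distance, the raw (unnormalised) cost, and
# the edit path that attains it. The exact engine enumerates node mappings by
# depth-first branch and bound; the bipartite engine solves one linear sum
# assignment problem whose substitution cells carry a local incident-edge
# term, then scores the edit path induced by the optimal assignment — a
# valid transformation, hence an upper bound on the exact distance.

ged_rep <- function(g) {
  n <- length(g$nodes)
  ids <- names(g$nodes)
  lab <- node_label_index(g$nodes)
  adj <- matrix(0L, n, n)
  if (nrow(g$edges) > 0L) {
    i <- match(g$edges$from, ids); j <- match(g$edges$to, ids)
    l <- edge_label_index(g$edges$label)
    adj[cbind(i, j)] <- l; adj[cbind(j, i)] <- l
  }
  list(n = n, ids = ids, lab = lab, adj = adj)
}

ged_result <- function(raw, path, method) {
  structure(list(distance = if (path$L == 0L) 0 else raw / path$L,
                 raw_cost = raw, path = path, method = method),
            class = "ged_result")
}

#' @export
print.ged_result <- function(x, ...) {
  cat(sprintf("ged_result (%s): distance %.6g (raw %.6g, L = %d, %d ops)\n",
              x$method, x$distance, x$raw_cost, x$path$L, nrow(x$path$ops)))
  invisible(x)
}

# Build the full edit path induced by a node mapping.
# map: integer vector over ga's nodes; map[i] in 1..n2 maps node i of ga to
# that node of gb, 0 deletes it. Unmatched gb nodes are inserted. Edge
# operations follow from the mapping; identity substitutions are recorded
# (they document the correspondence) but cost nothing.
mapping_to_path <- function(ga, gb, map) {
  A <- ged_rep(ga); B <- ged_rep(gb)
  rows <- vector("list", 0L)
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  for (i in seq_len(A$n)) {
    if (map[i] > 0L) {
      j <- map[i]
      add(op_row("node", "sub", erg_node_labels[A$lab[i]],
                 erg_node_labels[B$lab[j]], A$ids[i], B$ids[j]))
    } else {
      add(op_row("node", "del", from_label = erg_node_labels[A$lab[i]],
                 id1 = A$ids[i]))
    }
  }
  matched_b <- map[map > 0L]
  inv <- integer(B$n)
  inv[matched_b] <- which(map > 0L)
  for (j in setdiff(seq_len(B$n), matched_b))
    add(op_row("node", "ins", to_label = erg_node_labels[B$lab[j]],
               id2 = B$ids[j]))

  if (A$n > 1L) for (u in seq_len(A$n - 1L)) for (v in (u + 1L):A$n) {
    al <- A$adj[u, v]
    if (al == 0L) next
    if (map[u] > 0L && map[v] > 0L) {
      bl <- B$adj[map[u], map[v]]
      if (bl > 0L)
        add(op_row("edge", "sub", erg_edge_labels[al], erg_edge_labels[bl],
                   B$ids[map[u]], B$ids[map[v]]))
      else
        add(op_row("edge", "del", from_label = erg_edge_labels[al],
                   id1 = A$ids[u], id2 = A$ids[v]))
    } else {
      add(op_row("edge", "del", from_label = erg_edge_labels[al],
                 id1 = A$ids[u], id2 = A$ids[v]))
    }
  }
  if (B$n > 1L) for (p in seq_len(B$n - 1L)) for (q in (p + 1L):B$n) {
    bl <- B$adj[p, q]
    if (bl == 0L) next
    both_matched <- inv[p] > 0L && inv[q] > 0L
    if (both_matched && A$adj[inv[p], inv[q]] > 0L) next  # handled above
    add(op_row("edge", "ins", to_label = erg_edge_labels[bl],
               id1 = B$ids[p], id2 = B$ids[q]))
  }
  ops <- if (length(rows) > 0L) do.call(rbind, rows) else empty_ops()
  edit_path(ops, L = A$n + B$n)
}

#' Exact Graph Edit Distance by branch and bound
#'
#' Explores every injective node mapping (including deletions and
#' insertions) depth first, pruning branches whose partial cost already
#' reaches the best complete mapping found. The returned distance is the true
#' minimum of the normalised edit cost; among equal-cost mappings the
#' lexicographically smallest (in source-node order, target candidates
#' ascending, deletion last) is kept, so results are deterministic.
#' Exponential in the node count: refuse pairs above `max_nodes` total nodes.
#'
#' @param ga,gb `erg_graph` objects.
#' @param costs A `cost_table`.
#' @param max_nodes Refusal bound on `erg_order(ga) + erg_order(gb)`
#'   (default 14).
#' @return A `ged_result` with `method = "exact"`.
#' @examples
#' a <- erg_graph("a", c(x = "[0]"))
#' b <- erg_graph("b", c(y = "[7]"))
#' exact_ged(a, b, harper_costs())$distance  # 3/2
#' @export
exact_ged <- function(ga, gb, costs, max_nodes = 14L) {
  A <- ged_rep(ga); B <- ged_rep(gb)
  if (A$n + B$n > max_nodes)
    stop(sprintf(paste0("graphs have %d total nodes, above the exact-solver ",
                        "bound of %d; use bipartite_ged()"), A$n + B$n, max_nodes),
         call. = FALSE)
  ns <- costs$node_sub; ni <- costs$node_indel
  es <- costs$edge_sub; ei <- costs$edge_indel

  best <- Inf
  best_map <- NULL
  map <- integer(A$n)
  used <- logical(B$n)

  # cost of completing a partial mapping at depth n1: unmatched gb nodes and
  # every gb edge with at least one unmatched endpoint are inserted
  completion <- function() {
    cc <- 0
    un <- which(!used)
    for (j in un) cc <- cc + ni[B$lab[j]]
    if (B$n > 1L) for (p in seq_len(B$n - 1L)) for (q in (p + 1L):B$n) {
      bl <- B$adj[p, q]
      if (bl > 0L && (!used[p] || !used[q])) cc <- cc + ei[bl]
    }
    cc
  }

  dfs <- function(i, acc) {
    if (acc >= best) return(invisible())
    if (i > A$n) {
      total <- acc + completion()
      if (total < best) { best <<- total; best_map <<- map[seq_len(A$n)] }
      return(invisible())
    }
    for (j in c(which(!used), 0L)) {
      if (j > 0L) {
        delta <- ns[A$lab[i], B$lab[j]]
        if (i > 1L) for (k in seq_len(i - 1L)) {
          al <- A$adj[i, k]
          if (map[k] > 0L) {
            bl <- B$adj[j, map[k]]
            if (al > 0L && bl > 0L) { if (al != bl) delta <- delta + es[al, bl] }
            else if (al > 0L) delta <- delta + ei[al]
            else if (bl > 0L) delta <- delta + ei[bl]
          } else if (al > 0L) delta <- delta + ei[al]
        }
        map[i] <<- j; used[j] <<- TRUE
        dfs(i + 1L, acc + delta)
        used[j] <<- FALSE
      } else {
        delta <- ni[A$lab[i]]
        if (i > 1L) for (k in seq_len(i - 1L)) {
          al <- A$adj[i, k]
          if (al > 0L) delta <- delta + ei[al]
          # gb edges incident to nodes matched later or never are handled at
          # the matching step or in completion()
        }
        map[i] <<- 0L
        dfs(i + 1L, acc + delta)
      }
    }
    invisible()
  }

  if (A$n == 0L) { best_map <- integer(0) } else dfs(1L, 0)
  path <- mapping_to_path(ga, gb, best_map)
  raw <- edit_path_cost(path, costs, normalize = FALSE)
  ged_result(raw, path, "exact")
}

# optimal assignment cost between two incident-edge label multisets,
# unmatched edges paying their insertion/deletion cost
edge_set_cost <- function(l1, l2, es, ei) {
  k1 <- length(l1); k2 <- length(l2)
  if (k1 == 0L && k2 == 0L) return(0)
  if (k1 == 0L) return(sum(ei[l2]))
  if (k2 == 0L) return(sum(ei[l1]))
  m <- matrix(0, k1 + k2, k1 + k2)
  for (r in seq_len(k1)) for (cc in seq_len(k2))
    m[r, cc] <- if (l1[r] == l2[cc]) 0 else es[l1[r], l2[cc]]
  for (r in seq_len(k1)) m[r, (k2 + 1L):(k2 + k1)] <- ei[l1[r]]
  for (cc in seq_len(k2)) m[(k1 + 1L):(k1 + k2), cc] <- ei[l2[cc]]
  sol <- clue::solve_LSAP(m)
  sum(m[cbind(seq_len(k1 + k2), sol)])
}

#' Bipartite approximation of the Graph Edit Distance
#'
#' The fast assignment-based method: an \eqn{(n_1+n_2)\times(n_1+n_2)} cost
#' matrix is built whose substitution cells hold the node substitution cost
#' plus the optimal assignment cost between the two nodes' incident-edge
#' label multisets, and whose deletion/insertion cells hold the node
#' insert/delete cost plus all incident edge insert/delete costs. The matrix
#' is solved optimally (Hungarian method), the induced node mapping is turned
#' into a full edit path, and that path's cost is returned. Because the
#' induced path is a valid transformation, the result is always an upper
#' bound on [exact_ged()], and equals it whenever the assignment happens to
#' induce an optimal mapping (always the case for edgeless graphs).
#'
#' The assignment, and hence the induced path, is computed on a canonically
#' ordered pair (the mapping is inverted when the query order is the other
#' way round), so `bipartite_ged(a, b)` and `bipartite_ged(b, a)` return
#' exactly the same distance: insert/delete costs are tied and substitution
#' costs unordered, so a reversed path costs the same.
#'
#' @inheritParams exact_ged
#' @return A `ged_result` with `method = "bipartite"`.
#' @export
bipartite_ged <- function(ga, gb, costs) {
  if (graph_sort_key(ga) > graph_sort_key(gb)) {
    rev_map <- bipartite_assignment(gb, ga, costs)
    map <- integer(erg_order(ga))
    hit <- rev_map > 0L
    map[rev_map[hit]] <- which(hit)
    path <- mapping_to_path(ga, gb, map)
    return(ged_result(edit_path_cost(path, costs, FALSE), path, "bipartite"))
  }
  map <- bipartite_assignment(ga, gb, costs)
  path <- mapping_to_path(ga, gb, map)
  ged_result(edit_path_cost(path, costs, FALSE), path, "bipartite")
}

# deterministic per-graph ordering key (structure, then id)
graph_sort_key <- function(g) {
  paste(c(length(g$nodes), names(g$nodes), g$nodes,
          g$edges$from, g$edges$to, g$edges$label, g$id), collapse = "\r")
}

# optimal node assignment of the bipartite construction: integer map over
# ga's nodes (index into gb, 0 = delete)
bipartite_assignment <- function(ga, gb, costs) {
  A <- ged_rep(ga); B <- ged_rep(gb)
  if (A$n == 0L || B$n == 0L) return(rep(0L, A$n))
  ns <- costs$node_sub; ni <- costs$node_indel
  es <- costs$edge_sub; ei <- costs$edge_indel
  n1 <- A$n; n2 <- B$n

  inc_a <- lapply(seq_len(n1), function(i) A$adj[i, ][A$adj[i, ] > 0L])
  inc_b <- lapply(seq_len(n2), function(j) B$adj[j, ][B$adj[j, ] > 0L])

  # a finite stand-in for infinity: larger than the all-indel transformation
  big <- sum(ni[A$lab]) + sum(ni[B$lab]) +
    sum(vapply(inc_a, function(x) sum(ei[x]), numeric(1))) +
    sum(vapply(inc_b, function(x) sum(ei[x]), numeric(1))) + 1

  m <- matrix(big, n1 + n2, n1 + n2)
  for (i in seq_len(n1)) for (j in seq_len(n2))
    m[i, j] <- ns[A$lab[i], B$lab[j]] + edge_set_cost(inc_a[[i]], inc_b[[j]], es, ei)
  for (i in seq_len(n1))
    m[i, n2 + i] <- ni[A$lab[i]] + sum(ei[inc_a[[i]]])
  for (j in seq_len(n2))
    m[n1 + j, j] <- ni[B$lab[j]] + sum(ei[inc_b[[j]]])
  m[(n1 + 1L):(n1 + n2), (n2 + 1L):(n2 + n1)] <- 0

  sol <- as.integer(clue::solve_LSAP(m))
  map <- integer(n1)
  for (i in seq_len(n1)) map[i] <- if (sol[i] <= n2) sol[i] else 0L
  map
}

#' Compute a GED by the chosen method
#'
#' @inheritParams exact_ged
#' @param method `"bipartite"` (default) or `"exact"`.
#' @return A `ged_result`.
#' @export
ged <- function(ga, gb, costs, method = c("bipartite", "exact")) {
  method <- match.arg(method)
  if (method == "exact") exact_ged(ga, gb, costs) else bipartite_ged(ga, gb, costs)
}

#' Pairwise normalised GED matrix
#'
#' @param graphs List of `erg_graph` objects.
#' @param costs A `cost_table`.
#' @param method `"bipartite"` or `"exact"`.
#' @return Symmetric numeric matrix with graph ids as dimnames.
#' @export
pairwise_ged <- function(graphs, costs, method = c("bipartite", "exact")) {
  method <- match.arg(method)
  n <- length(graphs)
  ids <- vapply(graphs, function(g) g$id, character(1))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- ged(graphs[[i]], graphs[[j]], costs, method)$distance
  }
  d
}

#' Export a pairwise-distance matrix as tabular text
#'
#' Tab-separated, graph ids as row and column headers, full precision.
#' @param d Matrix from [pairwise_ged()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(id = rownames(d),
                   apply(d, 2, format, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
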