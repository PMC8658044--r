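# Seeded synthetic ErG populations.
#
# Real screening benchmarks cannot be redistributed here, so tests and
# examples run on generated two-class graph populations that mimic their
# structure: each class descends from a prototype graph with a biased
# pharmacophore-label composition (actives rich in aromatic/hydrophobic
# features, inactives in donor/acceptor/charge features), and individual
# molecules are prototypes perturbed by a known number of edit operations.
# Because the applied edit script is returned alongside each perturbed
# graph, these fixtures double as oracles: the script's cost is a certified
# upper bound on the exact GED between prototype and perturbation.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generation parameters for a synthetic two-class dataset
#'
#' @param seed Integer seed; identical specs generate identical datasets.
#' @param n_per_class Molecules per class (default 10).
#' @param prototype_order Nodes in each class prototype (default 8).
#' @param perturb_ops Edit operations applied to the prototype per sampled
#'   molecule (default 1). Keeping this well below `prototype_order`
#'   preserves class separability with high probability.
#' @param edge_density Probability of each non-tree edge in prototypes
#'   (default 0.35).
#' @param label_weights_active,label_weights_inactive Sampling weights over
#'   [erg_node_labels] for the two prototypes. The defaults bias actives
#'   towards aromatic rings, hydrophobic groups and link nodes, and
#'   inactives towards donors, acceptors and charges, so the class signal
#'   lives in label composition — the quantity the edit-cost table can
#'   learn to weigh.
#' @param proto_divergence `NULL` (default) draws the two prototypes
#'   independently from their label weights — a well-separated regime. A
#'   positive integer instead derives the inactive prototype from the active
#'   one by resampling exactly that many node labels (from the inactive
#'   weights): classes then differ by a planted label subset of known size,
#'   and once `perturb_ops` is comparable to it the classes overlap and a
#'   label-blind cost table misclassifies part of the population — the hard
#'   regime used to exercise cost learning.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, n_per_class = 10L, prototype_order = 8L,
                           perturb_ops = 1L, edge_density = 0.35,
                           label_weights_active = NULL,
                           label_weights_inactive = NULL,
                           proto_divergence = NULL) {
  stopifnot(n_per_class >= 1L, prototype_order >= 1L, perturb_ops >= 0L,
            edge_density >= 0, edge_density <= 1,
            is.null(proto_divergence) ||
              (proto_divergence >= 1L && proto_divergence <= prototype_order))
  if (is.null(label_weights_active)) {
    label_weights_active <- rep(0.2, 15)
    names(label_weights_active) <- erg_node_labels
    label_weights_active[c("[5]", "[4]", "[6]")] <- c(4, 3, 3)
  }
  if (is.null(label_weights_inactive)) {
    label_weights_inactive <- rep(0.2, 15)
    names(label_weights_inactive) <- erg_node_labels
    label_weights_inactive[c("[0]", "[1]", "[2]")] <- c(4, 3, 3)
  }
  structure(list(seed = as.integer(seed), n_per_class = as.integer(n_per_class),
                 prototype_order = as.integer(prototype_order),
                 perturb_ops = as.integer(perturb_ops),
                 edge_density = edge_density,
                 label_weights_active = label_weights_active,
                 label_weights_inactive = label_weights_inactive,
                 proto_divergence = if (is.null(proto_divergence)) NULL
                                    else as.integer(proto_divergence)),
            class = "generator_spec")
}

#' Generate a random connected ErG
#'
#' A random spanning tree over `order` nodes plus independent extra edges
#' with probability `edge_density`, with node labels sampled from
#' `label_weights` and edge labels biased towards single bonds.
#'
#' @param seed Integer seed.
#' @param order Number of nodes (>= 1).
#' @param edge_density Probability of each non-tree edge, in \[0, 1\].
#' @param label_weights Optional sampling weights over [erg_node_labels].
#' @param id Graph id (default derived from the seed).
#' @return A valid connected `erg_graph`.
#' @export
random_erg <- function(seed, order, edge_density = 0.3, label_weights = NULL,
                       id = sprintf("rg%d", seed)) {
  stopifnot(order >= 1L, edge_density >= 0, edge_density <= 1)
  with_seed(seed, random_erg_stream(order, edge_density, label_weights, id))
}

# body of random_erg drawing from the current RNG stream
random_erg_stream <- function(order, edge_density, label_weights, id) {
  labels <- sample(erg_node_labels, order, replace = TRUE, prob = label_weights)
  names(labels) <- paste0("n", seq_len(order))
  ef <- et <- el <- character(0)
  edge_lab <- function(k) sample(erg_edge_labels, k, replace = TRUE,
                                 prob = c(0.8, 0.15, 0.05))
  if (order > 1L) {
    for (k in 2:order) {  # spanning tree: attach each node to an earlier one
      a <- if (k == 2L) 1L else sample.int(k - 1L, 1L)
      ef <- c(ef, paste0("n", a)); et <- c(et, paste0("n", k))
    }
    for (u in seq_len(order - 1L)) for (v in (u + 1L):order) {
      tree <- any(ef == paste0("n", u) & et == paste0("n", v))
      if (!tree && stats::runif(1) < edge_density) {
        ef <- c(ef, paste0("n", u)); et <- c(et, paste0("n", v))
      }
    }
    el <- edge_lab(length(ef))
  }
  edges <- if (length(ef) > 0L)
    data.frame(from = ef, to = et, label = el, stringsAsFactors = FALSE)
  else NULL
  erg_graph(id, labels, edges)
}

#' Perturb an ErG by a known edit script
#'
#' Applies `n_ops` randomly chosen edit operations (node/edge substitution,
#' deletion, insertion) and returns both the perturbed graph and the applied
#' script as an `edit_path`. Operations act on distinct original elements —
#' an element inserted or already edited by this call is never edited again —
#' so the script is directly applicable via [apply_edit_path()] and its cost
#' under any table upper-bounds the exact GED between input and output.
#' Infeasible draws (e.g. an edge deletion on an edgeless graph) are
#' resampled; if no operation is feasible the script is cut short and the
#' result carries attribute `ops_applied` with the achieved count.
#'
#' @param g An `erg_graph`.
#' @param n_ops Number of operations to apply (>= 0).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return List with `graph` (the perturbed `erg_graph`) and `path` (the
#'   applied `edit_path`, normaliser `erg_order(g) + erg_order(result)`).
#' @export
perturb_graph <- function(g, n_ops, seed = NULL) {
  stopifnot(n_ops >= 0L)
  if (!is.null(seed)) return(with_seed(seed, perturb_stream(g, n_ops)))
  perturb_stream(g, n_ops)
}

perturb_stream <- function(g, n_ops) {
  nodes <- g$nodes
  edges <- g$edges
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  avail_nodes <- names(nodes)
  avail_edges <- if (nrow(edges) > 0L) ekey(edges$from, edges$to) else character(0)
  ops <- list()
  ins_counter <- 0L
  applied <- 0L

  for (step in seq_len(n_ops)) {
    if (n_ops == 0L) break
    ekeys <- if (nrow(edges) > 0L) ekey(edges$from, edges$to) else character(0)
    # nodes deletable without touching inserted/edited edges
    deletable <- Filter(function(nd) {
      inc <- ekeys[edges$from == nd | edges$to == nd]
      length(nodes) > 1L && all(inc %in% avail_edges)
    }, avail_nodes)
    nonadj <- if (length(nodes) > 1L) {
      prs <- utils::combn(names(nodes), 2L)
      keep <- !(ekey(prs[1L, ], prs[2L, ]) %in% ekeys)
      prs[, keep, drop = FALSE]
    } else matrix(character(0), nrow = 2L)

    feasible <- c(
      if (length(avail_nodes) > 0L) "node_sub",
      if (length(deletable) > 0L) "node_del",
      "node_ins",
      if (length(avail_edges) > 0L) c("edge_sub", "edge_del"),
      if (ncol(nonadj) > 0L) "edge_ins")
    if (length(feasible) == 0L) break
    op <- sample(feasible, 1L)

    if (op == "node_sub") {
      nd <- sample(avail_nodes, 1L)
      new <- sample(setdiff(erg_node_labels, nodes[[nd]]), 1L)
      ops[[length(ops) + 1L]] <- op_row("node", "sub", nodes[[nd]], new, nd, nd)
      nodes[[nd]] <- new
      avail_nodes <- setdiff(avail_nodes, nd)
    } else if (op == "node_del") {
      nd <- sample(deletable, 1L)
      inc <- which(edges$from == nd | edges$to == nd)
      for (i in inc)
        ops[[length(ops) + 1L]] <- op_row("edge", "del",
                                          from_label = edges$label[i],
                                          id1 = edges$from[i], id2 = edges$to[i])
      ops[[length(ops) + 1L]] <- op_row("node", "del",
                                        from_label = nodes[[nd]], id1 = nd)
      avail_edges <- setdiff(avail_edges, ekey(edges$from[inc], edges$to[inc]))
      if (length(inc) > 0L) edges <- edges[-inc, , drop = FALSE]
      nodes <- nodes[names(nodes) != nd]
      avail_nodes <- setdiff(avail_nodes, nd)
    } else if (op == "node_ins") {
      ins_counter <- ins_counter + 1L
      nd <- paste0("p", ins_counter)
      lab <- sample(erg_node_labels, 1L)
      ops[[length(ops) + 1L]] <- op_row("node", "ins", to_label = lab, id2 = nd)
      if (length(nodes) > 0L) {  # attach to keep the graph connected
        anchor <- sample(names(nodes), 1L)
        elab <- sample(erg_edge_labels, 1L, prob = c(0.8, 0.15, 0.05))
        ops[[length(ops) + 1L]] <- op_row("edge", "ins", to_label = elab,
                                          id1 = anchor, id2 = nd)
        edges <- rbind(edges, data.frame(from = anchor, to = nd, label = elab,
                                         stringsAsFactors = FALSE))
      }
      nodes <- c(nodes, stats::setNames(lab, nd))
    } else if (op == "edge_sub") {
      key <- sample(avail_edges, 1L)
      i <- match(key, ekeys)
      new <- sample(setdiff(erg_edge_labels, edges$label[i]), 1L)
      ops[[length(ops) + 1L]] <- op_row("edge", "sub", edges$label[i], new,
                                        edges$from[i], edges$to[i])
      edges$label[i] <- new
      avail_edges <- setdiff(avail_edges, key)
    } else if (op == "edge_del") {
      key <- sample(avail_edges, 1L)
      i <- match(key, ekeys)
      ops[[length(ops) + 1L]] <- op_row("edge", "del",
                                        from_label = edges$label[i],
                                        id1 = edges$from[i], id2 = edges$to[i])
      edges <- edges[-i, , drop = FALSE]
      avail_edges <- setdiff(avail_edges, key)
    } else {  # edge_ins
      pick <- sample.int(ncol(nonadj), 1L)
      u <- nonadj[1L, pick]; v <- nonadj[2L, pick]
      elab <- sample(erg_edge_labels, 1L, prob = c(0.8, 0.15, 0.05))
      ops[[length(ops) + 1L]] <- op_row("edge", "ins", to_label = elab,
                                        id1 = u, id2 = v)
      edges <- rbind(edges, data.frame(from = u, to = v, label = elab,
                                       stringsAsFactors = FALSE))
    }
    applied <- applied + 1L
  }

  out <- erg_graph(paste0(g$id, "~"), nodes,
                   if (nrow(edges) > 0L) edges else NULL, class = g$class)
  opdf <- if (length(ops) > 0L) do.call(rbind, ops) else empty_ops()
  res <- list(graph = out,
              path = edit_path(opdf, L = erg_order(g) + erg_order(out)))
  attr(res, "ops_applied") <- applied
  res
}

#' Generate a labeled two-class dataset
#'
#' Draws one prototype per class (with the spec's class-specific label
#' weights), samples each molecule by perturbing its class prototype with
#' `perturb_ops` edit operations, and splits each class into train and test
#' halves by alternation, so both classes appear in both halves. Actives are
#' labeled `"active"`, the decoy class `"inactive"`. The whole dataset is a
#' pure function of the spec.
#'
#' @param spec A [generator_spec()].
#' @return An `erg_dataset` named `"synth<seed>"`.
#' @export
make_two_class_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    proto_a <- random_erg_stream(spec$prototype_order, spec$edge_density,
                                 spec$label_weights_active, "protoA")
    proto_b <- if (is.null(spec$proto_divergence)) {
      random_erg_stream(spec$prototype_order, spec$edge_density,
                        spec$label_weights_inactive, "protoB")
    } else {
      # shared topology, planted label difference of known size
      pb <- proto_a
      pb$id <- "protoB"
      flip <- sample(names(pb$nodes), spec$proto_divergence)
      for (nd in flip)
        pb$nodes[[nd]] <- sample(
          setdiff(erg_node_labels, pb$nodes[[nd]]), 1L,
          prob = spec$label_weights_inactive[setdiff(erg_node_labels, pb$nodes[[nd]])])
      pb
    }
    make_class <- function(proto, prefix, cls) {
      lapply(seq_len(spec$n_per_class), function(i) {
        g <- perturb_stream(proto, spec$perturb_ops)$graph
        g$id <- sprintf("%s%02d", prefix, i)
        g$class <- cls
        g
      })
    }
    act <- make_class(proto_a, "A", "active")
    ina <- make_class(proto_b, "B", "inactive")
    odd <- function(lst) lst[seq_along(lst) %% 2L == 1L]
    even <- function(lst) lst[seq_along(lst) %% 2L == 0L]
    train <- c(odd(act), odd(ina))
    test <- c(even(act), even(ina))
    if (length(test) == 0L) {  # n_per_class == 1: duplicate-free fallback
      stop("n_per_class must be >= 2 to populate both halves", call. = FALSE)
    }
    erg_dataset(sprintf("synth%d", spec$seed), train, test)
  })
}
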