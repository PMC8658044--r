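# Iterative edit-cost learning.
#
# Each iteration classifies every training molecule against the rest of the
# training set (leave-one-out nearest neighbour), picks the misclassified
# molecule whose nearest same-class distance D' exceeds its nearest
# different-class distance D by the least, and updates the costs so that the
# two fixed edit paths swap their costs: D becomes D' and vice versa. The
# per-kind increments are
#     alpha_t  = (D' - D) * L  / (m  * N_t )   for kinds on the D path,
#     alpha_t' = (D - D') * L' / (m' * N_t')   for kinds on the D' path,
# where N_t are the operation counts of the realizing paths, L the
# normalisers, and m, m' the number of distinct kinds used. Kinds on both
# paths receive the average of the two increments. Counts are held fixed
# during the update; the paths are not re-optimised.

#' Nearest same-class and different-class distances of one molecule
#'
#' Computes D, the minimal GED from `g` to any training molecule of the
#' other class, and D', the minimal GED to any training molecule of its own
#' class (excluding `g` itself by id), together with the realizing edit
#' paths. The molecule is misclassified by the nearest-neighbour rule
#' exactly when D' > D.
#'
#' @param g A classed `erg_graph`.
#' @param train List of classed `erg_graph` objects containing at least one
#'   molecule of each class besides `g`.
#' @param costs A `cost_table`.
#' @param method `"bipartite"` (default) or `"exact"`.
#' @return An object of class `neighbor_pair`: list with `id`, `D`, `Dp`,
#'   `q_id`, `p_id`, `path_q`, `path_p`, `misclassified`.
#' @export
neighbor_distances <- function(g, train, costs,
                               method = c("bipartite", "exact")) {
  method <- match.arg(method)
  others <- Filter(function(x) x$id != g$id, train)
  cls <- vapply(others, function(x) x$class, character(1))
  if (!all(c("active", "inactive") %in% cls))
    stop("train must contain both classes besides '", g$id, "'", call. = FALSE)
  res <- lapply(others, function(x) ged(g, x, costs, method))
  d <- vapply(res, function(r) r$distance, numeric(1))
  same <- cls == g$class
  iq <- which(!same)[which.min(d[!same])]
  ip <- which(same)[which.min(d[same])]
  structure(list(id = g$id,
                 D = unname(d[iq]), Dp = unname(d[ip]),
                 q_id = others[[iq]]$id, p_id = others[[ip]]$id,
                 path_q = res[[iq]]$path, path_p = res[[ip]]$path,
                 misclassified = d[ip] > d[iq]),
            class = "neighbor_pair")
}

#' Select the molecule to repair
#'
#' Among misclassified molecules (D' > D), the one minimising the gap
#' D' - D: the molecule needing the smallest cost modification, chosen so
#' each iteration perturbs the cost table as little as possible. Ties go to
#' the lowest input index.
#'
#' @param pairs List of `neighbor_pair` objects.
#' @return The selected `neighbor_pair`, or `NULL` when nothing is
#'   misclassified.
#' @export
select_molecule <- function(pairs) {
  mis <- vapply(pairs, function(p) isTRUE(p$misclassified), logical(1))
  if (!any(mis)) return(NULL)
  gaps <- vapply(pairs, function(p) p$Dp - p$D, numeric(1))
  gaps[!mis] <- Inf
  pairs[[which.min(gaps)]]
}

#' Per-kind cost increments for one misclassified molecule
#'
#' Evaluates the swap increments from the two realizing paths' operation
#' counts. All `alpha` values are positive and all `alpha_p` values negative
#' (D' > D). They satisfy the reconstruction identities
#' `sum(alpha * N) / L == Dp - D` and `sum(alpha_p * N') / L' == D - Dp`.
#'
#' @param pair A misclassified `neighbor_pair`.
#' @return An object of class `alpha_update`: list with named numeric
#'   vectors `alphas` (kinds on the D path) and `alphas_p` (kinds on the D'
#'   path), integers `m`, `mp`, and the `D`, `Dp`, `L`, `Lp`, `counts_q`,
#'   `counts_p` they were computed from.
#' @export
compute_alphas <- function(pair) {
  if (!isTRUE(pair$misclassified))
    stop("molecule '", pair$id, "' is not misclassified (D' <= D)", call. = FALSE)
  counts_q <- path_kind_counts(pair$path_q)
  counts_p <- path_kind_counts(pair$path_p)
  m <- length(counts_q); mp <- length(counts_p)
  if (m == 0L || mp == 0L)
    stop(structure(class = c("degenerate_path_error", "error", "condition"),
                   list(message = sprintf(
                     "molecule '%s': a realizing path has no costed operations (m = %d, m' = %d)",
                     pair$id, m, mp), call = NULL)))
  L <- pair$path_q$L; Lp <- pair$path_p$L
  gap <- unname(pair$Dp - pair$D)
  alphas <- gap * L / (m * counts_q)
  alphas_p <- -gap * Lp / (mp * counts_p)
  structure(list(alphas = alphas, alphas_p = alphas_p, m = m, mp = mp,
                 D = pair$D, Dp = pair$Dp, L = L, Lp = Lp,
                 counts_q = counts_q, counts_p = counts_p),
            class = "alpha_update")
}

#' Apply an alpha update to a cost table
#'
#' Kinds appearing only on the D path gain their `alpha`; kinds only on the
#' D' path gain their (negative) `alpha_p`; kinds on both gain the average
#' of the two. All other parameters are untouched, and identity
#' substitutions stay structurally at 0. Updated values are clamped at 0
#' (costs are penalties); a warning reports any clamping.
#'
#' @param costs A `cost_table`.
#' @param upd An `alpha_update`.
#' @param clamp Clamp negative results at 0? Default `TRUE`.
#' @return The updated `cost_table` (provenance suffixed `"+updated"` once).
#' @export
apply_update <- function(costs, upd, clamp = TRUE) {
  kinds <- union(names(upd$alphas), names(upd$alphas_p))
  clamped <- character(0)
  for (k in kinds) {
    in_q <- k %in% names(upd$alphas)
    in_p <- k %in% names(upd$alphas_p)
    delta <- if (in_q && in_p) (upd$alphas[[k]] + upd$alphas_p[[k]]) / 2
             else if (in_q) upd$alphas[[k]]
             else upd$alphas_p[[k]]
    val <- cost_of(costs, k) + delta
    if (val < 0) {
      if (clamp) { clamped <- c(clamped, k); val <- 0 }
    }
    costs <- set_cost(costs, k, val)
  }
  if (length(clamped) > 0L)
    warning("clamped ", length(clamped), " cost(s) at 0: ",
            paste(clamped, collapse = ", "), call. = FALSE)
  if (!endsWith(costs$provenance, "+updated"))
    costs$provenance <- paste0(costs$provenance, "+updated")
  costs
}

# pairwise distances plus per-pair kind counts and normalisers, computed once
# per learning iteration (counts are direction-invariant: substitutions are
# unordered and insert/delete share a parameter)
pairwise_ged_detail <- function(graphs, costs, method) {
  n <- length(graphs)
  d <- matrix(0, n, n)
  counts <- vector("list", n * n); dim(counts) <- c(n, n)
  Ls <- matrix(0L, n, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- ged(graphs[[i]], graphs[[j]], costs, method)
    d[i, j] <- d[j, i] <- r$distance
    ct <- path_kind_counts(r$path)
    counts[[i, j]] <- counts[[j, i]] <- ct
    Ls[i, j] <- Ls[j, i] <- r$path$L
  }
  list(d = d, counts = counts, L = Ls)
}

#' Learn the full edit-cost table from a training set
#'
#' Runs the iterative repair loop: leave-one-out nearest-neighbour
#' classification of the training set, selection of the misclassified
#' molecule with the smallest distance gap, swap-based cost update, for at
#' most `max_iter` iterations (the reference protocol uses 50). Stops early
#' when no molecule is misclassified. Convergence is not guaranteed — the
#' cost table may oscillate — so the returned trace records the selected
#' molecule, its distances, the training accuracy and a cost snapshot at
#' every iteration for diagnosis.
#'
#' @param train List of classed `erg_graph` objects with both classes
#'   present.
#' @param init Initial `cost_table` (e.g. [harper_costs()] or
#'   [uniform_costs()]).
#' @param max_iter Maximum iterations, default 50.
#' @param method `"bipartite"` (default) or `"exact"`.
#' @param clamp Clamp negative costs at 0 (default `TRUE`).
#' @param snapshots Keep a per-iteration copy of the cost table? Default
#'   `TRUE`.
#' @return An object of class `learning_trace`: list with `iterations`
#'   (data frame `iter`, `selected`, `D`, `Dp`, `accuracy`), `snapshots`
#'   (list of `cost_table`s, post-update), `final` (the learnt
#'   `cost_table`) and `converged_early`.
#' @export
learn_costs <- function(train, init, max_iter = 50L,
                        method = c("bipartite", "exact"), clamp = TRUE,
                        snapshots = TRUE) {
  method <- match.arg(method)
  stopifnot(max_iter >= 1L)
  cls <- vapply(train, function(g) g$class, character(1))
  if (length(unique(cls)) < 2L)
    stop("train must contain both classes", call. = FALSE)
  n <- length(train)
  costs <- init
  rows <- list(); snaps <- list()
  converged_early <- FALSE

  for (it in seq_len(max_iter)) {
    det <- pairwise_ged_detail(train, costs, method)
    d <- det$d; diag(d) <- Inf

    nn_idx <- apply(d, 1L, which.min)
    acc <- 100 * mean(cls[nn_idx] == cls)

    # D / D' per molecule from the same distance matrix
    selected <- NULL
    gaps <- rep(Inf, n); Ds <- Dps <- rep(NA_real_, n); qs <- ps <- rep(NA_integer_, n)
    for (j in seq_len(n)) {
      same <- cls == cls[j]; same[j] <- FALSE
      diff <- cls != cls[j]
      iq <- which(diff)[which.min(d[j, diff])]
      ip <- which(same)[which.min(d[j, same])]
      Ds[j] <- d[j, iq]; Dps[j] <- d[j, ip]; qs[j] <- iq; ps[j] <- ip
      if (Dps[j] > Ds[j]) gaps[j] <- Dps[j] - Ds[j]
    }

    if (all(is.infinite(gaps))) {
      rows[[length(rows) + 1L]] <- data.frame(
        iter = it, selected = NA_character_, D = NA_real_, Dp = NA_real_,
        accuracy = acc, stringsAsFactors = FALSE)
      if (snapshots) snaps[[length(snaps) + 1L]] <- costs
      converged_early <- TRUE
      break
    }

    # walk candidates by increasing gap, skipping degenerate (empty) paths
    upd <- NULL; sel <- NA_integer_
    for (j in order(gaps)) {
      if (is.infinite(gaps[j])) break
      pair <- structure(list(
        id = train[[j]]$id, D = Ds[j], Dp = Dps[j],
        q_id = train[[qs[j]]]$id, p_id = train[[ps[j]]]$id,
        path_q = structure(list(ops = NULL, L = det$L[j, qs[j]]), class = "edit_path"),
        path_p = structure(list(ops = NULL, L = det$L[j, ps[j]]), class = "edit_path"),
        misclassified = TRUE), class = "neighbor_pair")
      # counts were tallied once by pairwise_ged_detail; inject them directly
      upd <- tryCatch(
        compute_alphas_from_counts(pair, det$counts[[j, qs[j]]],
                                   det$counts[[j, ps[j]]]),
        degenerate_path_error = function(e) { warning(conditionMessage(e), call. = FALSE); NULL })
      if (!is.null(upd)) { sel <- j; break }
    }

    if (is.null(upd)) {  # every misclassified molecule was degenerate
      rows[[length(rows) + 1L]] <- data.frame(
        iter = it, selected = NA_character_, D = NA_real_, Dp = NA_real_,
        accuracy = acc, stringsAsFactors = FALSE)
      if (snapshots) snaps[[length(snaps) + 1L]] <- costs
      converged_early <- TRUE
      break
    }

    costs <- apply_update(costs, upd, clamp = clamp)
    rows[[length(rows) + 1L]] <- data.frame(
      iter = it, selected = train[[sel]]$id, D = Ds[sel], Dp = Dps[sel],
      accuracy = acc, stringsAsFactors = FALSE)
    if (snapshots) snaps[[length(snaps) + 1L]] <- costs
  }

  costs$provenance <- sub("\\+updated$", "+learned", costs$provenance)
  structure(list(iterations = do.call(rbind, rows), snapshots = snaps,
                 final = costs, converged_early = converged_early),
            class = "learning_trace")
}

# compute_alphas() working from pre-tallied counts (learning inner loop)
compute_alphas_from_counts <- function(pair, counts_q, counts_p) {
  m <- length(counts_q); mp <- length(counts_p)
  if (m == 0L || mp == 0L)
    stop(structure(class = c("degenerate_path_error", "error", "condition"),
                   list(message = sprintf(
                     "molecule '%s': a realizing path has no costed operations (m = %d, m' = %d)",
                     pair$id, m, mp), call = NULL)))
  L <- pair$path_q$L; Lp <- pair$path_p$L
  gap <- unname(pair$Dp - pair$D)
  structure(list(alphas = gap * L / (m * counts_q),
                 alphas_p = -gap * Lp / (mp * counts_p),
                 m = m, mp = mp, D = pair$D, Dp = pair$Dp, L = L, Lp = Lp,
                 counts_q = counts_q, counts_p = counts_p),
            class = "alpha_update")
}

#' @export
print.learning_trace <- function(x, ...) {
  it <- x$iterations
  cat(sprintf("learning_trace: %d iteration(s)%s, accuracy %.1f%% -> %.1f%%\n",
              nrow(it), if (x$converged_early) " (converged early)" else "",
              it$accuracy[1L], it$accuracy[nrow(it)]))
  invisible(x)
}

#' Export a learning trace as tabular text
#'
#' One row per iteration: iteration index, selected molecule, D, D' and the
#' training accuracy under the costs in force at the start of the iteration.
#' @param trace A `learning_trace`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace$iterations, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
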