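h <- harper_costs()

# Hand-built training triplet: from the query molecule [6]-[6], the molecule
# [6]=[6] is one edge substitution away (raw 3, L = 4) and the molecule [6]
# is one node deletion away (raw 1 + free single-bond deletion, L = 3).
triplet <- function(g_class, q_class, p_class) {
  list(g = path_graph("g", c("[6]", "[6]"), class = g_class),
       q = path_graph("q", c("[6]", "[6]"), "=", class = q_class),
       p = path_graph("p", "[6]", class = p_class))
}

test_that("neighbor distances equal the normalized single-operation costs", {
  tr <- triplet("active", "inactive", "active")
  np <- neighbor_distances(tr$g, tr, h, method = "exact")
  expect_equal(np$D, 3 / 4)        # nearest different-class: edge sub
  expect_equal(np$Dp, 1 / 3)       # nearest same-class: node indel
  expect_identical(np$q_id, "q")
  expect_identical(np$p_id, "p")
  expect_false(np$misclassified)   # D' < D: correctly classified
})

test_that("a molecule with D' > D is flagged misclassified", {
  tr <- triplet("active", "active", "inactive")
  np <- neighbor_distances(tr$g, tr, h, method = "exact")
  expect_equal(np$D, 1 / 3)
  expect_equal(np$Dp, 3 / 4)
  expect_true(np$misclassified)
})

test_that("molecule selection takes the smallest positive gap, lowest index first", {
  mk <- function(id, D, Dp) structure(list(id = id, D = D, Dp = Dp,
                                           misclassified = Dp > D),
                                      class = "neighbor_pair")
  expect_null(select_molecule(list(mk("a", 1, 0.5), mk("b", 1, 1))))
  sel <- select_molecule(list(mk("a", 1, 1.5), mk("b", 1, 1.1), mk("c", 1, 1.3)))
  expect_identical(sel$id, "b")
  sel <- select_molecule(list(mk("a", 1, 1.2), mk("b", 1, 1.2)))
  expect_identical(sel$id, "a")
})

test_that("alpha increments follow the swap formula and reconstruction identities", {
  # path with a single operation kind used twice: alpha = gap * L / (m * N)
  two_dels <- edit_path(rbind(op_row("node", "del", from_label = "[0]"),
                              op_row("node", "del", from_label = "[0]")), L = 4L)
  one_sub <- edit_path(op_row("edge", "sub", "-", "="), L = 2L)
  pair <- structure(list(id = "m", D = 0.1, Dp = 0.6, q_id = "q", p_id = "p",
                         path_q = two_dels, path_p = one_sub,
                         misclassified = TRUE), class = "neighbor_pair")
  upd <- compute_alphas(pair)
  expect_equal(unname(upd$alphas[["ni:[0]"]]), 0.5 * 4 / (1 * 2))
  expect_equal(upd$m, 1L)
  expect_equal(upd$mp, 1L)
  expect_true(all(upd$alphas > 0) && all(upd$alphas_p < 0))
  # sum alpha_t N_t / L = Dp - D and sum alpha'_t N'_t / L' = D - Dp
  expect_equal(sum(upd$alphas * upd$counts_q) / upd$L, 0.5, tolerance = 1e-9)
  expect_equal(sum(upd$alphas_p * upd$counts_p) / upd$Lp, -0.5, tolerance = 1e-9)
  expect_equal(sum(upd$alphas * upd$counts_q) / upd$L +
               sum(upd$alphas_p * upd$counts_p) / upd$Lp, 0, tolerance = 1e-12)
})

test_that("alpha computation rejects non-misclassified and degenerate pairs", {
  ok_path <- edit_path(op_row("edge", "sub", "-", "="), L = 2L)
  not_mis <- structure(list(id = "m", D = 0.6, Dp = 0.6, path_q = ok_path,
                            path_p = ok_path, misclassified = FALSE),
                       class = "neighbor_pair")
  expect_error(compute_alphas(not_mis), "not misclassified")
  degen <- structure(list(id = "m", D = 0, Dp = 0.5,
                          path_q = edit_path(empty_ops(), L = 4L),
                          path_p = ok_path, misclassified = TRUE),
                     class = "neighbor_pair")
  expect_error(compute_alphas(degen), class = "degenerate_path_error")
})

test_that("the cost update applies alphas per the three-case rule", {
  upd <- structure(list(alphas = c("ni:[0]" = 1.0, "es:-|=" = 0.4),
                        alphas_p = c("es:-|=" = -0.2, "ei:=" = -0.5)),
                   class = "alpha_update")
  ct <- uniform_costs(2)
  out <- apply_update(ct, upd)
  expect_equal(cost_of(out, "ni:[0]"), 3.0)            # only on the D path
  expect_equal(cost_of(out, "es:-|="), 2.1)            # both: +(0.4 - 0.2)/2
  expect_equal(cost_of(out, "ei:="), 1.5)              # only on the D' path
  expect_equal(cost_of(out, "ni:[1]"), 2)              # untouched
  # symmetry and diagonals survive the update
  expect_identical(validate_cost_table(out), character(0))
})

test_that("negative results clamp at zero with a warning", {
  upd <- structure(list(alphas = numeric(0), alphas_p = c("ei:=" = -5)),
                   class = "alpha_update")
  expect_warning(out <- apply_update(harper_costs(), upd), "clamped")
  expect_equal(cost_of(out, "ei:="), 0)
  expect_equal(cost_of(apply_update(harper_costs(), upd, clamp = FALSE), "ei:="),
               -4, tolerance = 1e-12)
})

test_that("disjoint-support updates swap the two fixed-path distances exactly", {
  tr <- triplet("active", "active", "inactive")
  np <- neighbor_distances(tr$g, tr, h, method = "exact")
  expect_true(np$misclassified)
  # supports: {node indel [6], edge indel -} vs {edge sub -/=} — disjoint
  upd <- compute_alphas(np)
  expect_length(intersect(names(upd$alphas), names(upd$alphas_p)), 0L)
  new_costs <- apply_update(h, upd)
  newD <- edit_path_cost(np$path_q, new_costs, normalize = TRUE)
  newDp <- edit_path_cost(np$path_p, new_costs, normalize = TRUE)
  expect_equal(newD, np$Dp, tolerance = 1e-12)
  expect_equal(newDp, np$D, tolerance = 1e-12)
})

test_that("a perfectly classified training set converges immediately", {
  ds <- make_two_class_dataset(generator_spec(seed = 7))
  tr <- learn_costs(ds$train, h, max_iter = 10L)
  expect_true(tr$converged_early)
  expect_equal(nrow(tr$iterations), 1L)
  expect_equal(tr$iterations$accuracy, 100)
  expect_true(is.na(tr$iterations$selected))
  expect_equal(tr$final$node_sub, h$node_sub)
  expect_equal(tr$final$edge_indel, h$edge_indel)
})

test_that("learning preserves structural cost invariants across iterations", {
  ds <- make_two_class_dataset(generator_spec(seed = 11, n_per_class = 6,
                                              perturb_ops = 3,
                                              proto_divergence = 2))
  tr <- suppressWarnings(learn_costs(ds$train, uniform_costs(1), max_iter = 15L))
  expect_s3_class(tr, "learning_trace")
  expect_true(all(c("iter", "selected", "D", "Dp", "accuracy") %in%
                  names(tr$iterations)))
  for (snap in tr$snapshots) {
    expect_true(all(diag(snap$node_sub) == 0))
    expect_true(all(diag(snap$edge_sub) == 0))
    expect_true(all(c(snap$node_sub, snap$node_indel,
                      snap$edge_sub, snap$edge_indel) >= 0))
    expect_identical(validate_cost_table(snap), character(0))
  }
  # a selected molecule's recorded distances satisfy the misclassification rule
  sel <- tr$iterations[!is.na(tr$iterations$selected), , drop = FALSE]
  if (nrow(sel) > 0L) expect_true(all(sel$Dp > sel$D))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, f)
  expect_equal(nrow(utils::read.table(f, header = TRUE, sep = "\t")),
               nrow(tr$iterations))
})

test_that("learning is deterministic given its inputs", {
  ds <- make_two_class_dataset(generator_spec(seed = 11, n_per_class = 6,
                                              perturb_ops = 3,
                                              proto_divergence = 2))
  t1 <- suppressWarnings(learn_costs(ds$train, uniform_costs(1), max_iter = 8L))
  t2 <- suppressWarnings(learn_costs(ds$train, uniform_costs(1), max_iter = 8L))
  expect_identical(t1$iterations, t2$iterations)
  expect_identical(t1$final$node_sub, t2$final$node_sub)
})
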