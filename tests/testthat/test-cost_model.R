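test_that("Harper defaults reproduce the published expert values", {
  h <- harper_costs()
  expect_equal(cost_of(h, kind_node_sub("[0]", "[7]")), 3)
  expect_equal(cost_of(h, kind_node_sub("[0]", "[1]")), 2)
  expect_equal(cost_of(h, kind_node_sub("[0]", "[0,1]")), 1)
  expect_equal(cost_of(h, kind_node_indel("[6]")), 1)
  expect_equal(cost_of(h, kind_node_indel("[0]")), 2)
  expect_equal(cost_of(h, kind_edge_indel("-")), 0)
  expect_equal(cost_of(h, kind_edge_indel("=")), 1)
  expect_equal(cost_of(h, kind_edge_sub("-", "=")), 3)
  expect_identical(validate_cost_table(h), character(0))
})

test_that("the learnable parameter count matches the alphabet combinatorics", {
  # C(15,2) node pairs + 15 tied indels + C(3,2) edge pairs + 3 tied indels
  expect_identical(n_cost_parameters(harper_costs()),
                   as.integer(choose(15, 2) + 15 + choose(3, 2) + 3))
  expect_identical(n_cost_parameters(harper_costs()), 126L)
  expect_length(ergged:::all_kind_keys(), 126L)
})

test_that("uniform tables behave as stated", {
  u1 <- uniform_costs(1)
  expect_equal(cost_of(u1, kind_node_sub("[0]", "[1]")), 1)
  expect_identical(u1$provenance, "ones")
  expect_equal(cost_of(uniform_costs(2), kind_edge_indel("=")), 2)
  u0 <- uniform_costs(0)
  g <- path_graph("g", c("[0]", "[5]"))
  g2 <- path_graph("h", c("[7]", "[1]", "[2]"))
  expect_equal(exact_ged(g, g2, u0)$distance, 0)
  expect_error(uniform_costs(-1))
})

test_that("mean_costs is the parameter-wise arithmetic mean", {
  h <- harper_costs()
  m <- mean_costs(list(h, h))
  expect_equal(m$node_sub, h$node_sub)
  expect_equal(m$node_indel, h$node_indel)
  expect_equal(mean_costs(list(uniform_costs(0), uniform_costs(2)))$node_indel,
               uniform_costs(1)$node_indel)
  expect_equal(cost_of(mean_costs(list(h, uniform_costs(1))),
                       kind_node_sub("[0]", "[7]")), 2)
  expect_error(mean_costs(list()), "non-empty")
})

test_that("cost tables round-trip through CSV bit-exactly", {
  f <- withr::local_tempfile(fileext = ".csv")
  h <- harper_costs()
  h <- ergged:::set_cost(h, kind_node_sub("[0]", "[1]"), 1 / 3)  # full precision
  write_cost_table(h, f)
  r <- read_cost_table(f)
  for (k in ergged:::all_kind_keys())
    expect_identical(cost_of(r, k), cost_of(h, k))
})

test_that("cost-table files are validated against the full schema", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_cost_table(harper_costs(), f)
  rows <- readLines(f)
  drop <- grep("^edge_indel,\"#T\"", rows)   # remove the triple-bond indel row
  writeLines(rows[-drop], f)
  expect_error(read_cost_table(f), "missing parameter.*ei")
  writeLines(sub("^node_indel,\"\\[6\\]\",\"\",1$",
                 "node_indel,\"[6]\",\"\",-1", rows), f)
  expect_error(read_cost_table(f), "negative")
  writeLines(c(rows, rows[grep("^node_indel,\"\\[6\\]\"", rows)]), f)
  expect_error(read_cost_table(f), "duplicate")
})

test_that("the packaged learned table has the published structure", {
  lt <- learned_costs()
  expect_identical(validate_cost_table(lt), character(0))
  expect_identical(n_cost_parameters(lt), 126L)
  expect_equal(lt$node_sub, t(lt$node_sub))
  expect_true(all(diag(lt$node_sub) == 0) && all(diag(lt$edge_sub) == 0))
  expect_true(all(c(lt$node_sub, lt$node_indel, lt$edge_sub, lt$edge_indel) >= 0))
  # spot values
  expect_equal(cost_of(lt, kind_node_indel("[5]")), 1.89)
  expect_equal(cost_of(lt, kind_edge_indel("=")), 1.02)
  expect_equal(cost_of(lt, kind_node_sub("[0]", "[0,1,2]")), 0.97)
  # the non-carbon link node row is untouched by learning
  expect_true(all(lt$node_sub["[7]", -8] == 3))
})
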