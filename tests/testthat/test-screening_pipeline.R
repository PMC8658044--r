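mols <- function(prefix, n, class) {
  lapply(seq_len(n), function(i)
    path_graph(sprintf("%s%03d", prefix, i), "[5]", class = class))
}

test_that("target capping follows the first-n protocol", {
  s <- subset_target(mols("a", 150, "active"), mols("i", 300, "inactive"),
                     cap = 100)
  expect_length(s$actives, 100L)
  expect_length(s$inactives, 100L)
  expect_identical(s$actives[[1]]$id, "a001")   # file order preserved
  expect_identical(s$inactives[[100]]$id, "i100")

  s2 <- subset_target(mols("a", 40, "active"), mols("i", 300, "inactive"),
                      cap = 100)
  expect_length(s2$actives, 40L)
  expect_length(s2$inactives, 40L)

  expect_error(subset_target(list(), mols("i", 10, "inactive"),
                             cap = 100, target = "CDK2"), "CDK2")
  expect_error(subset_target(mols("a", 20, "active"), mols("i", 5, "inactive"),
                             cap = 100, target = "CHK1"), "CHK1")
})

test_that("experiments report per-target, per-dataset and grand means consistently", {
  t1 <- make_two_class_dataset(generator_spec(seed = 21, n_per_class = 4))
  t1$name <- "T1"
  t2 <- make_two_class_dataset(generator_spec(seed = 22, n_per_class = 4))
  t2$name <- "T2"
  cfg <- experiment_config(list(dsA = list(t1), dsB = list(t2)),
                           init = harper_costs(), max_iter = 3L)
  rep <- suppressWarnings(run_experiment(cfg))
  expect_s3_class(rep, "experiment_report")
  expect_equal(nrow(rep$per_target), 2L)
  expect_true(all(is.na(rep$per_target$error)))
  expect_identical(rep$costs$provenance, "mean")
  # report means recompute exactly from per-target rows
  for (d in rep$per_dataset_mean$dataset) {
    rows <- rep$per_target[rep$per_target$dataset == d, ]
    expect_equal(rep$per_dataset_mean$accuracy[rep$per_dataset_mean$dataset == d],
                 mean(rows$accuracy))
  }
  expect_equal(rep$grand_mean, mean(rep$per_dataset_mean$accuracy))
})

test_that("identical datasets give a mean table equal to the individual table", {
  tg <- make_two_class_dataset(generator_spec(seed = 31, n_per_class = 4))
  cfg <- experiment_config(list(d1 = list(tg), d2 = list(tg)),
                           init = harper_costs(), max_iter = 2L)
  rep <- suppressWarnings(run_experiment(cfg))
  one <- rep$per_dataset_costs[["d1"]]
  expect_equal(rep$costs$node_sub, one$node_sub)
  expect_equal(rep$costs$node_indel, one$node_indel)
  expect_equal(rep$costs$edge_sub, one$edge_sub)
  expect_equal(rep$costs$edge_indel, one$edge_indel)
})

test_that("experiments are reproducible and exportable", {
  tg <- make_two_class_dataset(generator_spec(seed = 41, n_per_class = 4))
  cfg <- experiment_config(list(d = list(tg)), init = uniform_costs(1),
                           max_iter = 3L)
  r1 <- suppressWarnings(run_experiment(cfg))
  r2 <- suppressWarnings(run_experiment(cfg))
  expect_identical(r1$per_target, r2$per_target)
  expect_identical(r1$grand_mean, r2$grand_mean)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(r1, f)
  expect_true(any(grepl("grand-mean", readLines(f))))
})

test_that("a failing target is reported, not dropped", {
  tg <- make_two_class_dataset(generator_spec(seed = 51, n_per_class = 4))
  broken <- tg
  broken$name <- "broken"
  broken$test <- lapply(broken$test, function(g) {
    if (g$class == "active") g$class <- "inactive"  # no actives left in test
    g
  })
  cfg <- experiment_config(list(d = list(tg, broken)), init = harper_costs(),
                           max_iter = 2L)
  rep <- suppressWarnings(run_experiment(cfg))
  expect_equal(nrow(rep$per_target), 2L)
  bad <- rep$per_target[rep$per_target$target == "broken", ]
  expect_true(is.na(bad$accuracy))
  expect_false(is.na(bad$error))
})
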