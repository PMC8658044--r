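test_that("minimal and worked-example graphs parse and round-trip", {
  f <- withr::local_tempfile(fileext = ".graphs")

  writeLines(c("graph m1", "n a [5]", ""), f)
  gs <- read_erg_graphs(f)
  expect_length(gs, 1L)
  expect_equal(erg_order(gs[[1]]), 1L)
  expect_equal(nrow(gs[[1]]$edges), 0L)
  expect_equal(unname(gs[[1]]$nodes), "[5]")

  # 4-node path transcription: file -> graph -> file is byte-stable
  write_erg_graphs(fig2_g1(), f)
  g <- read_erg_graphs(f)[[1]]
  expect_true(erg_identical(g, fig2_g1()))
  expect_equal(erg_order(g), 4L)
  expect_equal(g$edges$label, rep("-", 3L))
  f2 <- withr::local_tempfile(fileext = ".graphs")
  write_erg_graphs(g, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("the shipped worked-example fixture matches the in-code transcription", {
  f <- system.file("extdata", "fig2_transcription.graphs", package = "ergged")
  gs <- read_erg_graphs(f)
  expect_length(gs, 2L)
  expect_true(erg_identical(gs[[1]], fig2_g1()))
  expect_true(erg_identical(gs[[2]], fig2_g2()))
})

test_that("triple bond accepts both the UTF-8 symbol and the #T alias", {
  f <- withr::local_tempfile(fileext = ".graphs")
  writeLines(c("graph t", "n a [0]", "n b [1]", "e a b #T", ""), f)
  g1 <- read_erg_graphs(f)[[1]]
  writeLines(c("graph t", "n a [0]", "n b [1]", "e a b ≡", ""), f)
  g2 <- read_erg_graphs(f)[[1]]
  expect_true(erg_identical(g1, g2))
  expect_equal(g1$edges$label, "≡")
})

test_that("parse errors name the offending symbol and line", {
  f <- withr::local_tempfile(fileext = ".graphs")
  writeLines(c("graph bad", "n a [0]", "n b [1]", "e a b #"), f)
  expect_error(read_erg_graphs(f), "'#'.*line 4")
  writeLines(c("graph bad", "n a [9]"), f)
  expect_error(read_erg_graphs(f), "\\[9\\]")
  writeLines(c("graph bad", "n a [0]", "n b [1]", "e a b -", "e b a ="), f)
  expect_error(read_erg_graphs(f), "duplicate edge")
})

test_that("graph construction enforces the closed label alphabets", {
  expect_error(erg_graph("g", c(a = "[8]")), "\\[8\\]")
  expect_error(erg_graph("g", c(a = "[0]", b = "[1]"),
                         data.frame(from = "a", to = "b", label = "~")), "'~'")
  expect_error(erg_graph("g", c(a = "[0]"), class = "maybe"), "class")
})

test_that("validate_graph reports violations naming the offending element", {
  good <- erg_graph("g", c(a = "[0]", b = "[1]"),
                    data.frame(from = "a", to = "b", label = "-"))
  expect_identical(validate_graph(good), character(0))
  # invalid structures built by hand to bypass the validating constructor
  loop <- structure(list(id = "g", nodes = c(a = "[0]"),
                         edges = data.frame(from = "a", to = "a", label = "-",
                                            stringsAsFactors = FALSE),
                         class = NA_character_), class = "erg_graph")
  expect_match(validate_graph(loop), "self-loop.*'a'", all = FALSE)
  dangling <- structure(list(id = "g", nodes = c(a = "[0]"),
                             edges = data.frame(from = "a", to = "z", label = "-",
                                                stringsAsFactors = FALSE),
                             class = NA_character_), class = "erg_graph")
  expect_match(validate_graph(dangling), "undeclared", all = FALSE)
})

test_that("datasets enforce id disjointness and two-class training halves", {
  a1 <- path_graph("a1", "[5]", class = "active")
  a2 <- path_graph("a2", "[5]", class = "active")
  b1 <- path_graph("b1", "[0]", class = "inactive")
  b2 <- path_graph("b2", "[0]", class = "inactive")
  ds <- erg_dataset("t", list(a1, b1), list(a2, b2))
  expect_s3_class(ds, "erg_dataset")
  expect_error(erg_dataset("t", list(a1, b1), list(a1, b2)), "share graph ids")
  expect_error(erg_dataset("t", list(a1, a2), list(b1, b2)), "both classes")
})

test_that("split files read into an id-to-half map", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\ttrain", "g2\ttest"), f)
  s <- read_split(f)
  expect_identical(s, c(g1 = "train", g2 = "test"))
  writeLines(c("g1\tvalidation"), f)
  expect_error(read_split(f), "train")
})
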