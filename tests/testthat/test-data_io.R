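test_that("edge lists are deduplicated, self-loops dropped, order deterministic", {
  f <- withr::local_tempfile(lines = c("A\tB", "B\tC", "B\tA"))
  net <- read_network(f)
  expect_equal(net$nodes, c("A", "B", "C"))
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$edges$from, c("A", "B"))
  expect_equal(net$edges$to, c("B", "C"))

  f2 <- withr::local_tempfile(lines = c("A\tA", "A\tB"))
  expect_warning(net2 <- read_network(f2), "self-loop")
  expect_equal(nrow(net2$edges), 1L)

  f3 <- withr::local_tempfile(lines = c("# only a comment"))
  expect_error(read_network(f3), "empty network")
})

test_that("SIF files and weighted edge lists parse", {
  f <- withr::local_tempfile(lines = c("A pp B C", "B pp C", "D"))
  net <- read_network(f, format = "sif")
  expect_equal(net$nodes, c("A", "B", "C", "D"))
  expect_equal(nrow(net$edges), 3L)

  fw <- withr::local_tempfile(lines = c("A\tB\t0.5", "B\tC\t1"))
  netw <- read_network(fw)
  expect_equal(netw$edges$weight, c(0.5, 1))
  expect_error(nm_network(data.frame(a = "A", b = "B", w = 1.5)), "\\[0, 1\\]")
})

test_that("network serialization round-trips node and edge sets", {
  set.seed(11)
  net <- random_weighted_network(20, p = 0.2)
  f <- withr::local_tempfile()
  write_network(net, f)
  back <- read_network(f)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
})

test_that("restrict_to_expressed removes undetected genes and their edges", {
  net <- nm_network(data.frame(from = c("A", "B", "C"), to = c("B", "C", "D")))
  m <- rbind(A = c(1, 2), B = c(3, 0), C = c(0, 0), D = c(0, 5))
  expr <- toy_expression(m, n1 = 1)
  res <- restrict_to_expressed(net, expr)
  expect_equal(res$nodes, c("A", "B", "D"))     # C all-zero, removed; D isolated, kept
  expect_equal(nrow(res$edges), 1L)
  expect_equal(res$edges$from, "A")

  # a node absent from the expression matrix is removed too
  net2 <- nm_network(data.frame(from = "A", to = "Z"), nodes = c("A", "Z"))
  res2 <- restrict_to_expressed(net2, expr)
  expect_equal(res2$nodes, "A")

  # never adds nodes or edges
  expect_true(all(res$nodes %in% net$nodes))
  expect_true(nrow(res$edges) <= nrow(net$edges))

  # min_frac filter
  res3 <- restrict_to_expressed(net, expr, min_expr = 0, min_frac = 1)
  expect_equal(res3$nodes, "A")
})

test_that("expression TSV parsing rejects duplicate genes and honours labels", {
  f <- withr::local_tempfile(lines = c("gene\ts1\ts2", "A\t1\t2", "A\t3\t4"))
  lab <- c(s1 = "mature", s2 = "immature")
  expect_error(read_expression(f, lab), "A")

  f2 <- withr::local_tempfile(lines = c("gene\ts1\ts2", "A\t1\t2", "B\t3\t4"))
  expr <- read_expression(f2, lab)
  expect_equal(dim(expr$matrix), c(2L, 2L))
  expect_equal(as.character(expr$labels), c("mature", "immature"))
  expect_error(nm_expression(matrix(-1, 1, 2, dimnames = list("A", c("x", "y"))),
                             c(x = "mature", y = "immature")), "negative")
})

test_that("MatrixMarket triplet input is read with row/column name files", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 3 3", "1 1 5", "2 2 1", "1 3 2"),
             file.path(dir, "m.mtx"))
  writeLines(c("gA", "gB"), file.path(dir, "genes.txt"))
  writeLines(c("c1", "c2", "c3"), file.path(dir, "barcodes.txt"))
  lab <- c(c1 = "mature", c2 = "immature", c3 = "immature")
  expr <- read_expression(file.path(dir, "m.mtx"), lab, format = "mtx")
  expect_equal(expr$matrix["gA", "c3"], 2)
  expect_equal(expr$matrix["gB", "c1"], 0)

  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 3 1", "5 1 5"), file.path(dir, "bad.mtx"))
  expect_error(read_expression(file.path(dir, "bad.mtx"), lab, format = "mtx"))
})

test_that("GMT collections parse and intersect with a universe", {
  f <- withr::local_tempfile(lines = c("setA\tdesc\tg1\tg2\tg3",
                                       "setB\tother\tg9"))
  sets <- read_gmt(f)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_warning(sets2 <- read_gmt(f, universe = c("g1", "g2")), "disjoint")
  expect_equal(names(sets2), "setA")
  fbad <- withr::local_tempfile(lines = "setA\tonlydesc")
  expect_error(read_gmt(fbad), "malformed")
})
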