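make_partition <- function(...) {
  mods <- list(...)
  assign <- integer(0)
  for (i in seq_along(mods))
    assign <- c(assign, stats::setNames(rep(i, length(mods[[i]])), mods[[i]]))
  nm_partition(assign)
}

test_that("direction calls use the exact signed-rank null and BH", {
  genes <- sprintf("g%02d", 1:25)
  part <- make_partition(genes)
  calls <- call_direction(part, stats::setNames(1:25, genes))
  # all-positive ranks: two-sided exact p = 2 / 2^25
  expect_equal(calls$p_wilcoxon, 2 / 2^25, tolerance = 1e-12)
  expect_equal(as.character(calls$direction), "mature-high")

  # perfectly symmetric scores: p = 1
  sym <- stats::setNames(c(1:12, -(1:12)), sprintf("h%02d", 1:24))
  calls2 <- call_direction(make_partition(names(sym)), sym)
  expect_equal(calls2$p_wilcoxon, 1)
  expect_equal(as.character(calls2$direction), "none")

  # all-zero module: p = 1 by convention
  z <- stats::setNames(rep(0, 10), sprintf("z%02d", 1:10))
  expect_equal(call_direction(make_partition(names(z)), z)$p_wilcoxon, 1)
})

test_that("BH correction follows the step-up rule", {
  expect_equal(p.adjust(c(0.01, 0.04), method = "BH"), c(0.02, 0.04))
  # two modules whose raw p-values are forced to differ: q ordering respected
  up <- sprintf("u%02d", 1:20); mix <- sprintf("m%02d", 1:20)
  s <- stats::setNames(c(rep(1, 20), c(rep(1, 11), rep(-1, 9)) * (1:20)/10), c(up, mix))
  calls <- call_direction(make_partition(up, mix), s)
  expect_equal(calls$q_bh, p.adjust(calls$p_wilcoxon, method = "BH"))
})

test_that("negating scores flips directions with identical p-values", {
  set.seed(3)
  g1 <- sprintf("a%02d", 1:20); g2 <- sprintf("b%02d", 1:20)
  s <- stats::setNames(c(rnorm(20, 2), rnorm(20, -1)), c(g1, g2))
  part <- make_partition(g1, g2)
  up <- call_direction(part, s)
  dn <- call_direction(part, -s)
  expect_equal(up$p_wilcoxon, dn$p_wilcoxon)
  flip <- c("mature-high" = "immature-high", "immature-high" = "mature-high",
            "none" = "none")
  expect_equal(as.character(dn$direction), unname(flip[as.character(up$direction)]))
})

test_that("ARI matches hand cases and the contingency formula's range", {
  p1 <- make_partition(c("a", "b"), c("c", "d"), c("e", "f"))
  expect_equal(partition_ari(p1, p1), 1)
  # one-cluster partition vs balanced split: chance agreement
  single <- nm_partition(stats::setNames(rep(1L, 6), letters[1:6]))
  expect_equal(partition_ari(p1, single), 0)
  # {ab|cd|ef} vs {ab|ce|df} against the brute-force pair counter
  p2 <- make_partition(c("a", "b"), c("c", "e"), c("d", "f"))
  expect_equal(partition_ari(p1, p2),
               ari_oracle(p1$assignment[letters[1:6]], p2$assignment[letters[1:6]]))
  expect_error(partition_ari(p1, make_partition(c("x", "y"))), "shared")
})

test_that("ARI equals brute force exhaustively at n = 5 and agrees with mclust", {
  parts <- all_partitions(5)
  ids <- letters[1:5]
  for (x in parts[seq(1, length(parts), by = 3)]) for (y in parts) {
    px <- stats::setNames(x, ids); py <- stats::setNames(y, ids)
    expect_equal(partition_ari(nm_partition(px), nm_partition(py)),
                 ari_oracle(x, y), tolerance = 1e-12)
  }
  skip_if_not_installed("mclust")
  set.seed(9)
  for (trial in 1:20) {
    x <- sample(1:3, 8, TRUE); y <- sample(1:3, 8, TRUE)
    if (length(unique(x)) == 1L && length(unique(y)) == 1L) next
    expect_equal(partition_ari(nm_partition(stats::setNames(x, letters[1:8])),
                               nm_partition(stats::setNames(y, letters[1:8]))),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

test_that("unassigned genes are excluded from ARI unless kept", {
  a1 <- stats::setNames(c(1, 1, 2, 2, 0, 0), letters[1:6])
  a2 <- stats::setNames(c(1, 1, 2, 2, 1, 2), letters[1:6])
  expect_equal(partition_ari(nm_partition(a1), nm_partition(a2)), 1)
  expect_lt(partition_ari(nm_partition(a1), nm_partition(a2),
                          keep_unassigned = TRUE), 1)
})

test_that("adversarial pairs require opposite directions and a shared parent", {
  set.seed(42)
  up <- sprintf("u%02d", 1:20); dn <- sprintf("d%02d", 1:20)
  nn <- sprintf("n%02d", 1:25)
  net <- nm_network(rbind(clique_edges(c(up, dn)), clique_edges(nn)))
  scores <- data.frame(gene = c(up, dn, nn),
                       s = c(rnorm(20, 5, .5), rnorm(20, -5, .5),
                             rep(c(-0.1, 0.1), length.out = 25)))
  detw <- detect_modules(net, scores, min_size = 15)
  det0 <- detect_modules(net, scores, min_size = 15, unit_weights = TRUE)
  calls <- call_direction(detw$partition, scores)
  afm <- adversarial_pairs(detw$partition, det0$partition, calls)
  expect_equal(nrow(afm), 1L)
  pm <- detw$partition$modules[[as.character(afm$module_mature)]]
  pi_ <- detw$partition$modules[[as.character(afm$module_immature)]]
  expect_true(all(pm %in% up) && all(pi_ %in% dn))
  parent <- det0$partition$modules[[as.character(afm$parent_module)]]
  expect_true(all(c(pm, pi_) %in% parent))

  # same-direction children of one parent are not adversarial
  calls2 <- calls
  calls2$direction[calls2$direction == "immature-high"] <- "mature-high"
  expect_equal(nrow(adversarial_pairs(detw$partition, det0$partition, calls2)), 0L)
})

test_that("NES is the indicator correlation and NSI is background-relative", {
  part <- make_partition(c("g1", "g2"), c("g3", "g4"))
  calls <- data.frame(module = 1:2, direction = factor(
    c("mature-high", "none"), levels = c("mature-high", "immature-high", "none")))
  panel <- rbind(g1 = c(5, 5, 0, 0, 0, 0),    # affine image of the indicator
                 g2 = c(7, 9, 1, 0, 2, 1),
                 g3 = c(3, 3, 3, 3, 3, 3),    # constant: NES 0 by convention
                 g4 = c(0, 1, 2, 1, 0, 2))
  types <- rep(c("neuron", "astro", "oligo"), each = 2)
  expect_warning(res <- neuron_specificity(part, calls, panel, types), "zero-variance")
  expect_equal(unname(res$nes["g1"]), 1, tolerance = 1e-12)
  expect_equal(unname(res$nes["g3"]), 0)
  bg <- mean(res$nes[c("g3", "g4")])
  expect_equal(res$nsi$nsi, mean(res$nes[c("g1", "g2")]) - bg, tolerance = 1e-12)
  expect_error(neuron_specificity(part, calls, panel, types, "absent-type"),
               "absent")
})

test_that("Fisher enrichment matches the hypergeometric tail", {
  universe <- sprintf("g%02d", 1:20)
  module <- universe[1:10]
  coll <- list(hit = module, miss = universe[11:20],
               null = universe[c(1:5, 11:15)])
  enr <- geneset_enrichment(module, coll, universe)
  expect_equal(enr$p[enr$set == "hit"], 1 / choose(20, 10), tolerance = 1e-12)
  # proportions equal in and out of the module: no enrichment
  expect_gt(enr$p[enr$set == "null"], 0.5)
  expect_equal(enr$q_bh, p.adjust(enr$p, "BH"))   # enr is sorted by p
  expect_error(geneset_enrichment(character(0), coll, universe), "empty")
  expect_warning(geneset_enrichment(module, c(coll, list(out = "zz")), universe),
                 "skipped")
})

test_that("signature terms demand specificity and maximal coverage", {
  gA <- sprintf("a%02d", 1:10); gB <- sprintf("b%02d", 1:10)
  part <- make_partition(gA, gB)
  universe <- c(gA, gB, sprintf("x%02d", 1:20))
  coll <- list(cov60 = gA[1:6], cov80 = gA[1:8],
               shared = c(gA, gB), small = gA[1:3])
  sig <- signature_term(part, coll, universe)
  # both cov60 and cov80 qualify for module 1; max coverage wins
  expect_equal(sig$signature[sig$module == 1], "cov80")
  expect_equal(sig$coverage[sig$module == 1], 0.8)
  # 'shared' is enriched in both modules, so module 2 has no specific term
  expect_true(is.na(sig$signature[sig$module == 2]))
})
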