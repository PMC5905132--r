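test_that("standardization follows the log10 training formula", {
  # train values {0, 99}: log10(e+1) = {0, 2}, mean 1, sd sqrt(2)
  stats_ <- list(mean_log = 1, sd_log = sqrt(2))
  expect_equal(standardize_expression(99, stats_$mean_log, stats_$sd_log),
               1 / sqrt(2), tolerance = 1e-12)
  # at the training mean the standardized value is 0
  expect_equal(standardize_expression(10^1 - 1, 1, sqrt(2)), 0)
  # constant training gene: 0 for any input
  expect_equal(standardize_expression(c(5, 50), 0.3, 0), c(0, 0))
  expect_error(standardize_expression(-1, 0, 1), "negative")
})

test_that("train/test split is stratified, seeded, and matches explicit counts", {
  set.seed(1)
  m <- matrix(rpois(10 * 241, 5), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("c%03d", 1:241)))
  expr <- toy_expression(m, n1 = 131)            # 131 mature, 110 immature
  sp <- split_train_test(expr, n_train = c(mature = 99, immature = 82), seed = 4)
  expect_equal(as.integer(table(sp$train$labels)[c("mature", "immature")]),
               c(99L, 82L))
  expect_equal(as.integer(table(sp$test$labels)[c("mature", "immature")]),
               c(32L, 28L))
  # identical seed, identical split
  sp2 <- split_train_test(expr, n_train = c(mature = 99, immature = 82), seed = 4)
  expect_identical(colnames(sp$train$matrix), colnames(sp2$train$matrix))
  expect_error(split_train_test(expr, train_frac = 1.2), "train_frac")
})

test_that("a perfectly separating gene reaches CV AUC 1 and weight 0.5", {
  set.seed(8)
  n <- 60
  sep <- c(rnorm(n / 2, 8, .2), rnorm(n / 2, 1, .2))   # mature always higher
  noise <- matrix(rpois(4 * n, 3), nrow = 4)
  m <- rbind(sep = 10^sep, noise)
  rownames(m) <- c("sep", sprintf("n%d", 1:4))
  expr <- toy_expression(m)
  model <- train_mnmi(expr, c("sep", "n1"), module_id = 1L, seed = 2)
  expect_equal(model$cv_auc, 1, tolerance = 1e-8)
  expect_equal(model$weight, 0.5, tolerance = 1e-8)
  expect_equal(evaluate_auc(predict_mnmi(model, expr), expr$labels), 1)
})

test_that("label-permuted training yields near-chance CV AUC", {
  set.seed(12)
  aucs <- replicate(10, {
    m <- matrix(rpois(6 * 80, 10), nrow = 6,
                dimnames = list(sprintf("g%d", 1:6), sprintf("c%d", 1:80)))
    expr <- toy_expression(m)
    train_mnmi(expr, rownames(m), seed = sample.int(1e6, 1))$cv_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("degenerate modules degrade to intercept-only models", {
  m <- rbind(flat = rep(3, 20), flat2 = rep(7, 20))
  rownames(m) <- c("flat", "flat2")
  expr <- toy_expression(m)
  model <- train_mnmi(expr, c("flat", "flat2"))
  expect_equal(model$weight, 0)
  expect_equal(model$cv_auc, 0.5)
  expect_true(all(model$coef == 0))
  p <- predict_mnmi(model, expr)
  expect_true(all(p == p[1]))
  expect_error(train_mnmi(expr, c("absent1", "absent2"), module_id = 9L), "9")
})

test_that("prediction is monotone in positive-coefficient genes and order invariant", {
  model <- structure(list(module = 1L, genes = c("gA", "gB"),
                          mean_log = c(1, 1), sd_log = c(0.5, 0.5),
                          intercept = -0.2, coef = c(gA = 1.5, gB = -0.7),
                          lambda = 0.01, cv_auc = 0.9, weight = 0.4),
                     class = "mnmi_model")
  m <- rbind(gA = c(1, 5, 40), gB = c(2, 2, 2))
  colnames(m) <- c("s1", "s2", "s3")
  p <- predict_mnmi(model, m)
  expect_true(all(diff(p) > 0))                 # raising gA raises mNMI
  perm <- m[c("gB", "gA"), c("s3", "s1", "s2")]
  expect_equal(predict_mnmi(model, perm)[colnames(m)], p)
  # sample at the training means scores plogis(intercept)
  at_mean <- matrix(10^1 - 1, 2, 1, dimnames = list(c("gA", "gB"), "x"))
  expect_equal(unname(predict_mnmi(model, at_mean)), plogis(-0.2))
  # missing genes are imputed at the training mean with a warning when >50%
  expect_warning(pm <- predict_mnmi(model, rbind(gZ = c(x = 1))), "absent")
  expect_equal(unname(pm), plogis(-0.2))
})

test_that("integration is the AUC-derived weighted mean and a convex combination", {
  mnmi <- cbind(m1 = c(0.9, 0.2), m2 = c(0.4, 0.8))
  # cv_auc (1.0, 0.5) -> weights (0.5, 0): second module ignored
  expect_equal(integrate_mnmi(mnmi, c(0.5, 0)), c(0.9, 0.2))
  # equal weights -> arithmetic mean
  expect_equal(integrate_mnmi(mnmi, c(0.3, 0.3)), c(0.65, 0.5))
  expect_error(integrate_mnmi(mnmi, c(0, 0)), "no informative")
  set.seed(77)
  for (trial in 1:20) {
    v <- matrix(runif(12), 3); w <- runif(4)
    out <- integrate_mnmi(v, w)
    expect_true(all(out >= apply(v, 1, min) - 1e-12 &
                    out <= apply(v, 1, max) + 1e-12))
  }
})

test_that("rank-based AUC handles ties and hand examples", {
  expect_equal(evaluate_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(evaluate_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(evaluate_auc(rep(0.5, 6), rep(c(0, 1), 3)), 0.5)
  expect_error(evaluate_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("model JSON round-trip reproduces predictions bit-exactly", {
  set.seed(19)
  tr <- synthetic_truth(n_modules = 2L, module_size = 10L, n_background = 10L,
                        effects = c(2, -2), n_cells = c(mature = 40, immature = 40),
                        seed = 5)
  expr <- simulate_expression(tr)
  part <- planted_partition(tr)
  calls <- call_direction(part, score_expression(expr))
  bundle <- train_nmi(expr, part, calls, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(bundle, f)
  back <- read_model(f)
  expect_identical(predict_nmi(back, expr), predict_nmi(bundle, expr))
  for (id in names(bundle$models)) {
    expect_identical(back$models[[id]]$coef, bundle$models[[id]]$coef)
    expect_identical(back$models[[id]]$mean_log, bundle$models[[id]]$mean_log)
  }
  expect_error(read_model(withr::local_tempfile(lines = "{\"schema\": \"x\"}")),
               "schema")
})

test_that("integrated indices respect their module subsets", {
  set.seed(23)
  tr <- synthetic_truth(n_modules = 3L, module_size = 12L, n_background = 6L,
                        effects = c(2, -2, 0), n_cells = c(mature = 50, immature = 50),
                        seed = 11)
  expr <- simulate_expression(tr)
  part <- planted_partition(tr)
  calls <- call_direction(part, score_expression(expr))
  bundle <- train_nmi(expr, part, calls, seed = 2)
  expect_true(all(bundle$mature_high %in% bundle$discriminating))
  pred <- predict_nmi(bundle, expr)
  cols <- paste0("mNMI_", bundle$discriminating)
  w <- vapply(bundle$models[as.character(bundle$discriminating)], `[[`, 0, "weight")
  expect_equal(pred$dNMI,
               unname(integrate_mnmi(as.matrix(pred[cols]), w)), tolerance = 1e-12)
})
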