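#' Standardize expression on the training scale
#'
#' `ehat = (log10(e + 1) - mean_log) / sd_log`, where `mean_log` and
#' `sd_log` are the mean and standard deviation of `log10(e + 1)` across
#' the training samples. Genes with `sd_log = 0` (constant in training)
#' standardize to 0 for any input.
#'
#' @param e nonnegative expression values (vector or genes x samples
#'   matrix, FPKM scale).
#' @param mean_log,sd_log training statistics (scalars for a vector `e`,
#'   or per-gene vectors matching `nrow(e)`).
#' @return standardized values with the shape of `e`.
#' @export
standardize_expression <- function(e, mean_log, sd_log) {
  if (any(e < 0)) stop("negative expression value")
  z <- log10(e + 1) - mean_log
  out <- z / ifelse(sd_log == 0, Inf, sd_log)
  out[is.nan(out)] <- 0
  out
}

train_standardization <- function(train_matrix) {
  lg <- log10(train_matrix + 1)
  list(mean_log = rowMeans(lg), sd_log = apply(lg, 1L, stats::sd))
}

#' Stratified train/test split
#'
#' Class-stratified random split of the samples. Either a training
#' fraction (per-class training size `round(n * train_frac)`) or explicit
#' per-class training counts may be given.
#'
#' @param expr an `nm_expression`.
#' @param train_frac fraction of each class assigned to training
#'   (default 0.75).
#' @param n_train optional named integer vector of per-class training
#'   counts (names = class labels); overrides `train_frac`.
#' @param seed integer seed; the same seed reproduces the same split.
#' @return list with `train` and `test` `nm_expression` objects.
#' @export
split_train_test <- function(expr, train_frac = 0.75, n_train = NULL, seed = 1L) {
  stopifnot(inherits(expr, "nm_expression"))
  if (is.null(n_train) && (train_frac <= 0 || train_frac >= 1))
    stop("train_frac must lie in (0, 1)")
  classes <- levels(expr$labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train_ids <- unlist(lapply(classes, function(cl) {
    ids <- names(expr$labels)[expr$labels == cl]
    if (length(ids) == 0L) stop("empty class: ", cl)
    k <- if (!is.null(n_train)) {
      if (!cl %in% names(n_train)) stop("n_train lacks class ", cl)
      as.integer(n_train[[cl]])
    } else round(length(ids) * train_frac)
    if (k < 1L || k >= length(ids))
      stop("class ", cl, ": training size leaves no train or no test samples")
    sample(ids, k)
  }))
  test_ids <- setdiff(colnames(expr$matrix), train_ids)
  subset_expr <- function(ids) nm_expression(
    expr$matrix[, ids, drop = FALSE],
    stats::setNames(as.character(expr$labels[ids]), ids),
    class1 = classes[2L], class0 = classes[1L])
  list(train = subset_expr(train_ids), test = subset_expr(test_ids))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Rank-based AUC of a score against binary labels
#'
#' Mann-Whitney AUC: the probability that a random positive scores above
#' a random negative, with ties counting 1/2.
#'
#' @param score numeric score per sample.
#' @param labels logical/0-1/factor labels; the second factor level (or
#'   `TRUE`/1) is the positive class.
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(score, labels) {
  pos <- if (is.factor(labels)) labels == levels(labels)[2L] else as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train a modular neuron maturity index (mNMI) model
#'
#' Fits an L1-penalized logistic regression of maturity class on the
#' standardized expression of the module's genes over a decreasing lambda
#' path (100 values down to 1e-4 of the null-model lambda), choosing the
#' lambda that maximizes mean AUC over seeded, class-stratified 10-fold
#' cross-validation, then refitting on the full training set. The model's
#' integration weight is `max(cv_auc - 0.5, 0)`.
#'
#' @param train an `nm_expression` training set.
#' @param module_genes character vector of the module's genes; genes
#'   absent from the training matrix are dropped (an error if none
#'   remain).
#' @param module_id identifier stored in the model (default `NA`).
#' @param n_folds CV folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return an `mnmi_model`: list with `module`, `genes`, `mean_log`,
#'   `sd_log`, `intercept`, `coef` (named, sparse in effect), `lambda`,
#'   `cv_auc`, `weight`.
#' @export
train_mnmi <- function(train, module_genes, module_id = NA_integer_,
                       n_folds = 10L, seed = 1L) {
  stopifnot(inherits(train, "nm_expression"))
  genes <- intersect(module_genes, rownames(train$matrix))
  if (length(genes) == 0L)
    stop("module ", module_id, ": no gene overlaps the training matrix")
  y <- as.integer(train$labels == levels(train$labels)[2L])
  std <- train_standardization(train$matrix[genes, , drop = FALSE])
  x <- t(standardize_expression(train$matrix[genes, , drop = FALSE],
                                std$mean_log, std$sd_log))
  colnames(x) <- genes
  model <- structure(list(module = module_id, genes = genes,
                          mean_log = unname(std$mean_log),
                          sd_log = unname(std$sd_log)),
                     class = "mnmi_model")
  if (all(std$sd_log == 0)) {
    # no informative feature: intercept-only model at the class base rate
    model$intercept <- stats::qlogis(mean(y))
    model$coef <- stats::setNames(rep(0, length(genes)), genes)
    model$lambda <- NA_real_; model$cv_auc <- 0.5; model$weight <- 0
    return(model)
  }
  # glmnet needs >= 2 predictor columns; pad single-gene modules with a
  # zero dummy that the lasso necessarily drops
  padded <- ncol(x) == 1L
  if (padded) x <- cbind(x, .dummy. = 0)
  foldid <- stratified_folds(y, n_folds, seed)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        standardize = FALSE, nlambda = 100L,
                        lambda.min.ratio = 1e-4)
  path <- fit$lambda
  # cross-validated linear predictors over the whole lambda path; the AUC
  # is computed on the pooled held-out predictions, which stays defined
  # for folds too small to carry their own ROC curve
  cvpred <- matrix(NA_real_, nrow(x), length(path))
  for (f in unique(foldid)) {
    hold <- foldid == f
    ffit <- glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold],
                           family = "binomial", alpha = 1,
                           standardize = FALSE, lambda = path)
    cvpred[hold, ] <- stats::predict(ffit, x[hold, , drop = FALSE], s = path,
                                     type = "link")
  }
  cv_auc_path <- apply(cvpred, 2L, evaluate_auc, labels = y)
  best <- which.max(cv_auc_path)   # first maximum: the sparsest such model
  lambda <- path[best]
  cf <- as.matrix(stats::coef(fit, s = lambda))[, 1L]
  model$intercept <- unname(cf[1L])
  beta <- cf[-1L]
  if (padded) beta <- beta[names(beta) != ".dummy."]
  model$coef <- stats::setNames(unname(beta), genes)
  model$coef[std$sd_log == 0] <- 0
  model$lambda <- lambda
  model$cv_auc <- unname(cv_auc_path[best])
  model$weight <- max(model$cv_auc - 0.5, 0)
  model
}

stratified_folds <- function(y, n_folds, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

#' @export
print.mnmi_model <- function(x, ...) {
  cat(sprintf("mnmi_model (module %s): %d genes, %d nonzero coefficients, CV AUC %.3f\n",
              x$module, length(x$genes), sum(x$coef != 0), x$cv_auc))
  invisible(x)
}

#' Predict mNMI for new samples
#'
#' Standardizes FPKM-scale expression with the model's training
#' statistics and applies the logistic model. Genes absent from the
#' input are imputed at the training mean (`ehat = 0`); a message reports
#' the count, escalated to a warning above 50% missing.
#'
#' @param model an `mnmi_model`.
#' @param expr an `nm_expression` or genes x samples matrix on the FPKM
#'   scale.
#' @return named numeric vector of per-sample maturity probabilities in
#'   (0, 1).
#' @export
predict_mnmi <- function(model, expr) {
  m <- if (inherits(expr, "nm_expression")) expr$matrix else as.matrix(expr)
  present <- intersect(model$genes, rownames(m))
  n_miss <- length(model$genes) - length(present)
  if (n_miss > 0L) {
    msg <- sprintf("module %s: %d/%d model gene(s) absent, imputed at training mean",
                   model$module, n_miss, length(model$genes))
    if (n_miss > length(model$genes) / 2) warning(msg) else message(msg)
  }
  eta <- rep(model$intercept, ncol(m))
  if (length(present)) {
    idx <- match(present, model$genes)
    ehat <- standardize_expression(m[present, , drop = FALSE],
                                   model$mean_log[idx], model$sd_log[idx])
    eta <- eta + drop(crossprod(ehat, model$coef[idx]))
  }
  stats::setNames(stats::plogis(eta), colnames(m))
}

#' Integrate mNMIs into a weighted index
#'
#' `iNMI = sum_i w_i mNMI_i / sum_i w_i` with `w_i = max(AUC_i - 0.5, 0)`
#' from cross-validation. A convex combination of its inputs.
#'
#' @param mnmi samples x modules matrix (or data.frame) of mNMI values.
#' @param weights per-module weights (`cv_auc - 0.5`, floored at 0).
#' @return named numeric vector of per-sample integrated indices.
#' @export
integrate_mnmi <- function(mnmi, weights) {
  mnmi <- as.matrix(mnmi)
  if (ncol(mnmi) == 0L || length(weights) != ncol(mnmi))
    stop("need one weight per module")
  weights <- pmax(weights, 0)
  if (sum(weights) == 0) stop("no informative modules (all weights zero)")
  drop(mnmi %*% weights) / sum(weights)
}

#' Train the full NMI bundle
#'
#' One mNMI model per module of the partition, with the module subsets
#' used by the integrated indices: tNMI (all modules), dNMI
#' (discriminating modules), NFI (mature-high modules).
#'
#' @param train an `nm_expression` training set.
#' @param partition an `nm_partition`.
#' @param calls direction calls from [call_direction()].
#' @inheritParams train_mnmi
#' @param alpha the alpha used for `calls` (stored as metadata).
#' @return an `nmi_bundle`: list with `models` (list of `mnmi_model`),
#'   `discriminating`, `mature_high` (integer module ids) and `alpha`.
#' @export
train_nmi <- function(train, partition, calls, n_folds = 10L, seed = 1L,
                      alpha = 0.05) {
  stopifnot(inherits(partition, "nm_partition"))
  ids <- as.integer(names(partition$modules))
  models <- lapply(ids, function(id)
    train_mnmi(train, partition$modules[[as.character(id)]], module_id = id,
               n_folds = n_folds, seed = seed + id))
  names(models) <- as.character(ids)
  structure(list(models = models,
                 discriminating = calls$module[calls$direction != "none"],
                 mature_high = calls$module[calls$direction == "mature-high"],
                 alpha = alpha),
            class = "nmi_bundle")
}

#' @export
print.nmi_bundle <- function(x, ...) {
  cat(sprintf("nmi_bundle: %d modules (%d discriminating, %d mature-high)\n",
              length(x$models), length(x$discriminating), length(x$mature_high)))
  invisible(x)
}

#' Predict integrated maturity indices
#'
#' @param bundle an `nmi_bundle`.
#' @param expr an `nm_expression` or FPKM-scale genes x samples matrix.
#' @return data.frame with one row per sample: `sample`, `tNMI`, `dNMI`,
#'   `NFI`, then one `mNMI_<module>` column per module. An integrated
#'   index is `NA` when its module subset is empty or carries no weight.
#' @export
predict_nmi <- function(bundle, expr) {
  stopifnot(inherits(bundle, "nmi_bundle"))
  mnmi <- vapply(bundle$models, predict_mnmi, expr = expr,
                 numeric(n_samples(expr)))
  if (is.null(dim(mnmi))) mnmi <- matrix(mnmi, nrow = 1L,
                                         dimnames = list(NULL, names(bundle$models)))
  w <- vapply(bundle$models, `[[`, 0, "weight")
  ids <- as.integer(names(bundle$models))
  integrate_subset <- function(subset) {
    sel <- ids %in% subset
    if (!any(sel) || sum(w[sel]) == 0) return(rep(NA_real_, nrow(mnmi)))
    integrate_mnmi(mnmi[, sel, drop = FALSE], w[sel])
  }
  out <- data.frame(sample = sample_names(expr, nrow(mnmi)),
                    tNMI = integrate_subset(ids),
                    dNMI = integrate_subset(bundle$discriminating),
                    NFI = integrate_subset(bundle$mature_high))
  colnames(mnmi) <- paste0("mNMI_", names(bundle$models))
  cbind(out, as.data.frame(mnmi), row.names = NULL)
}

n_samples <- function(expr) {
  if (inherits(expr, "nm_expression")) ncol(expr$matrix) else ncol(as.matrix(expr))
}
sample_names <- function(expr, n) {
  nm <- if (inherits(expr, "nm_expression")) colnames(expr$matrix) else colnames(expr)
  if (is.null(nm)) paste0("sample", seq_len(n)) else nm
}

#' Serialize / restore an NMI bundle as JSON
#'
#' The JSON round-trip preserves coefficients and standardization
#' parameters bit-exactly, so predictions are identical.
#'
#' @param bundle an `nmi_bundle`.
#' @param path JSON file path.
#' @return `read_model` returns the restored `nmi_bundle`.
#' @export
write_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "nmi_bundle"))
  obj <- list(schema = "netmature-nmi/1",
              version = as.character(utils::packageVersion("netmature")),
              alpha = bundle$alpha,
              discriminating = as.integer(bundle$discriminating),
              mature_high = as.integer(bundle$mature_high),
              models = lapply(unname(bundle$models), function(m)
                list(module = m$module, genes = m$genes,
                     mean_log = m$mean_log, sd_log = m$sd_log,
                     intercept = m$intercept, coef = unname(m$coef),
                     lambda = m$lambda, cv_auc = m$cv_auc, weight = m$weight)))
  # digits = I(17) round-trips IEEE doubles exactly, so restored models
  # predict bit-identically
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$schema, "netmature-nmi/1"))
    stop("unrecognized model schema: ", obj$schema)
  models <- lapply(obj$models, function(m) {
    structure(list(module = as.integer(m$module), genes = as.character(m$genes),
                   mean_log = as.numeric(m$mean_log), sd_log = as.numeric(m$sd_log),
                   intercept = as.numeric(m$intercept),
                   coef = stats::setNames(as.numeric(m$coef), as.character(m$genes)),
                   lambda = if (is.null(m$lambda)) NA_real_ else as.numeric(m$lambda),
                   cv_auc = as.numeric(m$cv_auc), weight = as.numeric(m$weight)),
              class = "mnmi_model")
  })
  names(models) <- vapply(models, function(m) as.character(m$module), "")
  structure(list(models = models,
                 discriminating = as.integer(obj$discriminating),
                 mature_high = as.integer(obj$mature_high),
                 alpha = as.numeric(obj$alpha)),
            class = "nmi_bundle")
}
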