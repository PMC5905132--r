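#' Validate a pipeline configuration
#'
#' Fills defaults and checks parameter ranges before any compute. A
#' configuration is a named list (or a YAML file holding one) with file
#' paths (`network`, `expression`, `labels`, optional `gmt`, `panel`,
#' `panel_types`, `outdir`) and parameters (`beta` 0.55, `min_size` 20,
#' `min_gap` 0.1, `alpha` 0.05, `pseudocount` 1, `n_folds` 10,
#' `train_frac` 0.75, `seed` 1, `target_type` "neuron", `min_expr` 0,
#' `min_frac` 0).
#'
#' @param config named list or YAML file path.
#' @return validated config list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(beta = 0.55, min_size = 20L, min_gap = 0.1, alpha = 0.05,
                   pseudocount = 1, n_folds = 10L, train_frac = 0.75,
                   seed = 1L, target_type = "neuron", min_expr = 0,
                   min_frac = 0, outdir = "netmature_out")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  with(config, {
    if (beta <= 0 || beta > 1) stop("config: beta must lie in (0, 1]")
    if (min_size < 2) stop("config: min_size must be >= 2")
    if (alpha <= 0 || alpha >= 1) stop("config: alpha must lie in (0, 1)")
    if (pseudocount <= 0) stop("config: pseudocount must be positive")
  })
  for (nm in c("network", "expression", "labels"))
    if (is.null(config[[nm]])) stop("config: missing required path '", nm, "'")
  config
}

#' Run the full pipeline
#'
#' score -> smooth -> modules (weighted and topology-only) -> direction
#' calls and adversarial pairs -> NMI training on a stratified split ->
#' prediction on the held-out samples. All outputs are written to
#' `config$outdir` as stamped TSVs plus `model.json` and a
#' `manifest.json` recording parameters, versions and seed; re-running
#' the same config reproduces them bit-identically.
#'
#' @param config see [validate_config()].
#' @return (invisibly) a list with the in-memory results: `scores`,
#'   `detection`, `calls`, `afm`, `bundle`, `prediction`, and optional
#'   `enrichment` / `nsi`.
#' @export
run_all <- function(config) {
  config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, fn) tryCatch(fn(), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  out <- function(f) file.path(config$outdir, f)
  stamp <- function(df, f) write_tsv_stamped(df, out(f), seed = config$seed,
                                             command = "run_all")

  net <- stage("read", function() read_network(config$network))
  expr <- stage("read", function() read_expression(config$expression, config$labels))
  net <- stage("restrict", function()
    restrict_to_expressed(net, expr, config$min_expr, config$min_frac))
  scores <- stage("score", function()
    score_expression(expr, pseudocount = config$pseudocount))
  stamp(scores, "scores.tsv")

  det <- stage("modules", function()
    detect_modules(net, scores, beta = config$beta, min_size = config$min_size,
                   min_gap = config$min_gap))
  det0 <- stage("modules", function()
    detect_modules(net, scores, beta = config$beta, min_size = config$min_size,
                   min_gap = config$min_gap, unit_weights = TRUE))
  shat <- det$diffusion$shat
  stamp(data.frame(gene = names(shat), shat = shat), "smoothed_scores.tsv")
  stamp(det$diffusion$network$edges, "weighted_edges.tsv")
  stamp(data.frame(gene = names(det$partition$assignment),
                   module = det$partition$assignment), "modules.tsv")

  calls <- stage("stats", function()
    call_direction(det$partition, scores, alpha = config$alpha))
  stamp(calls, "module_calls.tsv")
  afm <- stage("stats", function()
    adversarial_pairs(det$partition, det0$partition, calls, alpha = config$alpha))
  stamp(afm, "afm_pairs.tsv")

  enr <- nsi <- NULL
  if (!is.null(config$gmt)) {
    sets <- stage("stats", function() read_gmt(config$gmt, universe = net$nodes))
    enr <- stage("stats", function() signature_term(det$partition, sets, net$nodes,
                                                    alpha = config$alpha))
    stamp(enr, "signature_terms.tsv")
  }
  if (!is.null(config$panel)) {
    panel <- stage("stats", function()
      utils::read.table(config$panel, header = TRUE, sep = "\t", row.names = 1L,
                        check.names = FALSE, comment.char = "#"))
    types <- stage("stats", function() {
      tl <- read_labels(config$panel_types)
      as.character(tl[colnames(panel)])
    })
    nsi <- stage("stats", function()
      neuron_specificity(det$partition, calls, as.matrix(panel), types,
                         config$target_type))
    stamp(nsi$nsi, "nsi.tsv")
  }

  split <- stage("train-nmi", function()
    split_train_test(expr, train_frac = config$train_frac, seed = config$seed))
  bundle <- stage("train-nmi", function()
    train_nmi(split$train, det$partition, calls, n_folds = config$n_folds,
              seed = config$seed, alpha = config$alpha))
  stage("train-nmi", function() write_model(bundle, out("model.json")))
  pred <- stage("predict-nmi", function() predict_nmi(bundle, split$test))
  stamp(pred, "nmi_test.tsv")

  manifest <- list(tool = "netmature",
                   version = as.character(utils::packageVersion("netmature")),
                   r_version = R.version.string,
                   seed = config$seed,
                   parameters = config[c("beta", "min_size", "min_gap", "alpha",
                                         "pseudocount", "n_folds", "train_frac",
                                         "min_expr", "min_frac")],
                   inputs = config[c("network", "expression", "labels")],
                   n_nodes = length(net$nodes),
                   n_modules = length(det$partition$modules),
                   n_discriminating = sum(calls$direction != "none"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(scores = scores, detection = det, detection_unweighted = det0,
                 calls = calls, afm = afm, enrichment = enr, nsi = nsi,
                 bundle = bundle, prediction = pred, config = config))
}

#' Write a synthetic benchmark dataset to disk
#'
#' Writes `network.tsv`, `expr.tsv`, `labels.tsv`, `panel.tsv`,
#' `panel_types.tsv`, `sets.gmt` and `truth.json` for a
#' [synthetic_truth()] preset, in the formats the pipeline reads.
#'
#' @param outdir output directory.
#' @param truth a [synthetic_truth()].
#' @return (invisibly) the output directory.
#' @export
simulate_to_dir <- function(outdir, truth = synthetic_truth()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dat <- simulate_dataset(truth)
  write_network(dat$network, file.path(outdir, "network.tsv"))
  expr_df <- data.frame(gene = rownames(dat$expression$matrix),
                        dat$expression$matrix, check.names = FALSE)
  utils::write.table(expr_df, file.path(outdir, "expr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(dat$expression$labels),
                                class = as.character(dat$expression$labels)),
                     file.path(outdir, "labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(gene = rownames(dat$panel$panel), dat$panel$panel,
                                check.names = FALSE),
                     file.path(outdir, "panel.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(dat$panel$panel),
                                type = dat$panel$type_labels),
                     file.path(outdir, "panel_types.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_gmt(dat$gene_sets, file.path(outdir, "sets.gmt"))
  jsonlite::write_json(list(planted = as.list(dat$truth$planted),
                            effects = as.list(dat$truth$effects),
                            seed = dat$truth$seed),
                       file.path(outdir, "truth.json"), auto_unbox = TRUE)
  invisible(outdir)
}
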