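#' Ground truth for a synthetic benchmark
#'
#' Defines a planted-partition network and a two-class expression design
#' with module-level directional effects. The defaults are the package's
#' reference study conditions: 5 planted modules of 30 genes plus 150
#' background genes, intra-module edge probability 0.3 against a 0.02
#' background, module effects of +2, +2, -2, -2 and 0 on the log2 scale,
#' and 100 cells per class.
#'
#' @param n_modules number of planted modules.
#' @param module_size genes per planted module.
#' @param n_background unplanted background genes.
#' @param p_in,p_out intra-/inter-module edge probabilities
#'   (`p_in > p_out`).
#' @param effects log2 expression shift of the mature class per module
#'   (length `n_modules`; 0 = null module).
#' @param n_cells named vector `c(mature = , immature = )` of cells per
#'   class.
#' @param baseline_mean,baseline_sd log2-scale mean and sd of per-gene
#'   baseline expression (FPKM scale ~ 2^N(mean, sd^2)).
#' @param dispersion negative-binomial size parameter (smaller = noisier).
#' @param dropout per-entry Bernoulli dropout probability.
#' @param seed integer seed; every generator is a pure function of
#'   (parameters, seed).
#' @return a `synthetic_truth` list; `planted` maps each gene to its
#'   module (0 = background) and `direction` labels each module up, down
#'   or null.
#' @export
synthetic_truth <- function(n_modules = 5L, module_size = 30L,
                            n_background = 150L, p_in = 0.3, p_out = 0.02,
                            effects = c(2, 2, -2, -2, 0),
                            n_cells = c(mature = 100L, immature = 100L),
                            baseline_mean = 3, baseline_sd = 1.5,
                            dispersion = 2, dropout = 0.2, seed = 1L) {
  if (p_in <= p_out) stop("p_in must exceed p_out")
  if (length(effects) != n_modules) stop("one effect per module required")
  n_genes <- n_modules * module_size + n_background
  genes <- sprintf("g%04d", seq_len(n_genes))
  planted <- stats::setNames(c(rep(seq_len(n_modules), each = module_size),
                               rep(0L, n_background)), genes)
  direction <- ifelse(effects > 0, "up", ifelse(effects < 0, "down", "null"))
  structure(list(genes = genes, planted = planted,
                 module_direction = stats::setNames(direction, seq_len(n_modules)),
                 effects = stats::setNames(effects, seq_len(n_modules)),
                 p_in = p_in, p_out = p_out, n_cells = n_cells,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 dispersion = dispersion, dropout = dropout, seed = seed),
            class = "synthetic_truth")
}

#' Planted-partition random network
#'
#' Gene pairs within a planted module are joined with probability `p_in`,
#' all other pairs with probability `p_out`. Deterministic given the
#' truth's seed.
#'
#' @param truth a [synthetic_truth()].
#' @return an [nm_network] over the truth's genes (all genes kept as
#'   nodes, including isolated ones).
#' @export
make_network <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(truth$seed)
  g <- truth$genes; n <- length(g)
  memb <- truth$planted[g]
  pairs <- utils::combn(n, 2L)
  same <- memb[pairs[1L, ]] == memb[pairs[2L, ]] & memb[pairs[1L, ]] != 0L
  prob <- ifelse(same, truth$p_in, truth$p_out)
  keep <- stats::runif(ncol(pairs)) < prob
  edges <- data.frame(from = g[pairs[1L, keep]], to = g[pairs[2L, keep]])
  nm_network(edges, nodes = g)
}

#' Simulate a two-class expression matrix with planted effects
#'
#' Each gene draws a log2 baseline from `N(baseline_mean, baseline_sd^2)`;
#' genes of an effect module have their mature-class mean shifted by the
#' module's effect (log2 units). FPKM-scale values are negative-binomial
#' draws at the class mean with the stated dispersion, zeroed by Bernoulli
#' dropout. Null-module and background genes are identically distributed
#' in both classes.
#'
#' @param truth a [synthetic_truth()].
#' @return an `nm_expression` with classes `mature` / `immature`.
#' @export
simulate_expression <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(truth$seed + 1L)
  g <- truth$genes; n <- length(g)
  base <- stats::rnorm(n, truth$baseline_mean, truth$baseline_sd)
  eff <- ifelse(truth$planted[g] == 0L, 0, truth$effects[as.character(truth$planted[g])])
  eff[is.na(eff)] <- 0
  n1 <- truth$n_cells[["mature"]]; n0 <- truth$n_cells[["immature"]]
  mu1 <- 2^(base + eff); mu0 <- 2^base
  draw <- function(mu, k) {
    m <- matrix(stats::rnbinom(n * k, mu = rep(mu, k), size = truth$dispersion),
                nrow = n)
    if (truth$dropout > 0)
      m[matrix(stats::runif(n * k) < truth$dropout, nrow = n)] <- 0
    m
  }
  mat <- cbind(draw(mu1, n1), draw(mu0, n0))
  dimnames(mat) <- list(g, c(sprintf("mat%03d", seq_len(n1)),
                             sprintf("imm%03d", seq_len(n0))))
  labels <- stats::setNames(rep(c("mature", "immature"), c(n1, n0)), colnames(mat))
  nm_expression(mat, labels)
}

#' Synthetic purified-cell-type reference panel
#'
#' A genes x (types x reps) panel in which genes of the effect (non-null)
#' planted modules are expressed highly in the target cell type and near
#' zero elsewhere, so their NES approaches 1; background and null-module
#' genes fluctuate around a flat baseline.
#'
#' @param truth a [synthetic_truth()].
#' @param n_types number of cell types (first one is the target).
#' @param reps replicate samples per type.
#' @param target_type name of the target type (default `"neuron"`).
#' @param noise_sd log2-scale noise sd.
#' @return list with `panel` (genes x samples matrix), `type_labels` and
#'   `target_type`.
#' @export
make_celltype_panel <- function(truth, n_types = 3L, reps = 4L,
                                target_type = "neuron", noise_sd = 0.25) {
  stopifnot(inherits(truth, "synthetic_truth"), n_types >= 2L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(truth$seed + 2L)
  g <- truth$genes; n <- length(g)
  types <- c(target_type, paste0("type", seq_len(n_types - 1L)))
  type_labels <- rep(types, each = reps)
  specific <- truth$planted[g] != 0L &
    truth$module_direction[as.character(truth$planted[g])] != "null"
  specific[is.na(specific)] <- FALSE
  base <- matrix(2^stats::rnorm(n * length(type_labels), 2, noise_sd), nrow = n)
  hi <- 2^(6 + stats::rnorm(sum(specific) * reps, 0, noise_sd))
  base[specific, type_labels == target_type] <-
    base[specific, type_labels == target_type] + hi
  dimnames(base) <- list(g, sprintf("%s_%d", type_labels,
                                    stats::ave(seq_along(type_labels),
                                               type_labels, FUN = seq_along)))
  list(panel = base, type_labels = type_labels, target_type = target_type)
}

#' Synthetic gene-set collection mirroring the planted modules
#'
#' One set per planted module holding a fraction `overlap` of the
#' module's genes, topped up with random background genes to the module
#' size; `overlap = 1` reproduces the module exactly, `overlap = 0`
#' yields sets unrelated to any module.
#'
#' @param truth a [synthetic_truth()].
#' @param overlap fraction of each set drawn from its module, in
#'   \[0, 1\].
#' @return named list of gene sets (a `description` attribute carries the
#'   planted module id).
#' @export
make_gene_sets <- function(truth, overlap = 1) {
  stopifnot(inherits(truth, "synthetic_truth"), overlap >= 0, overlap <= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(truth$seed + 3L)
  bg <- names(truth$planted)[truth$planted == 0L]
  ids <- sort(unique(truth$planted[truth$planted != 0L]))
  sets <- lapply(ids, function(id) {
    memb <- names(truth$planted)[truth$planted == id]
    k <- round(overlap * length(memb))
    own <- if (k > 0) sample(memb, k) else character(0)
    fill <- sample(bg, length(memb) - k)
    sort(c(own, fill))
  })
  names(sets) <- sprintf("planted_set_%d", ids)
  attr(sets, "description") <- stats::setNames(sprintf("module %d", ids), names(sets))
  sets
}

#' Generate a complete synthetic benchmark dataset
#'
#' @param truth a [synthetic_truth()]; defaults to the reference preset.
#' @return list with `truth`, `network`, `expression`, `panel` (see
#'   [make_celltype_panel()]) and `gene_sets`.
#' @export
simulate_dataset <- function(truth = synthetic_truth()) {
  list(truth = truth,
       network = make_network(truth),
       expression = simulate_expression(truth),
       panel = make_celltype_panel(truth),
       gene_sets = make_gene_sets(truth))
}

#' Planted partition as an `nm_partition`
#' @param truth a [synthetic_truth()].
#' @export
planted_partition <- function(truth) nm_partition(truth$planted, min_size = 2L)
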