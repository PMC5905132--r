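#' Call module direction by signed-rank test
#'
#' For each module, a two-sided Wilcoxon signed-rank test of the member
#' genes' expression alteration scores against a zero median, with
#' Benjamini-Hochberg correction across modules. Modules with BH-adjusted
#' p below `alpha` are "discriminating": mature-high when the median score
#' is positive, immature-high when negative.
#'
#' @param partition an `nm_partition`.
#' @param scores data.frame with `gene` and `s` columns, or a named
#'   numeric score vector.
#' @param alpha BH significance threshold (default 0.05).
#' @param use_smoothed when `scores` is a data.frame holding a `shat`
#'   column, test the smoothed scores instead of the raw ones.
#' @return data.frame with one row per module: `module`, `n_genes`,
#'   `median_s`, `p_wilcoxon`, `q_bh`, `direction` (factor with levels
#'   mature-high / immature-high / none).
#' @export
call_direction <- function(partition, scores, alpha = 0.05,
                           use_smoothed = FALSE) {
  stopifnot(inherits(partition, "nm_partition"))
  s <- score_vector(scores, use_smoothed)
  calls <- lapply(names(partition$modules), function(id) {
    genes <- partition$modules[[id]]
    sv <- s[intersect(genes, names(s))]
    med <- stats::median(sv)
    nz <- sv[sv != 0]
    p <- if (length(nz) < 1L) 1 else
      suppressWarnings(stats::wilcox.test(sv, mu = 0)$p.value)
    data.frame(module = as.integer(id), n_genes = length(genes),
               median_s = med, p_wilcoxon = p)
  })
  out <- do.call(rbind, calls)
  if (is.null(out)) stop("partition has no modules")
  out$q_bh <- stats::p.adjust(out$p_wilcoxon, method = "BH")
  dir <- rep("none", nrow(out))
  sig <- out$q_bh < alpha
  dir[sig & out$median_s > 0] <- "mature-high"
  dir[sig & out$median_s < 0] <- "immature-high"
  # significant module with an exactly-zero median: direction by mean sign
  zed <- sig & out$median_s == 0
  if (any(zed)) {
    mean_sign <- vapply(out$module[zed], function(id)
      sign(mean(s[intersect(partition$modules[[as.character(id)]], names(s))])), 0)
    dir[zed] <- ifelse(mean_sign > 0, "mature-high",
                       ifelse(mean_sign < 0, "immature-high", "none"))
  }
  out$direction <- factor(dir, levels = c("mature-high", "immature-high", "none"))
  rownames(out) <- NULL
  out
}

score_vector <- function(scores, use_smoothed = FALSE) {
  if (is.data.frame(scores)) {
    col <- if (use_smoothed) "shat" else "s"
    if (!col %in% names(scores)) stop("scores lack a '", col, "' column")
    stats::setNames(scores[[col]], scores$gene)
  } else {
    if (is.null(names(scores))) stop("score vector must be named by gene")
    scores
  }
}

#' Hubert-Arabie adjusted Rand index between two partitions
#'
#' Computed from the contingency table over the shared gene universe.
#' Unassigned genes (module 0) are by default removed from both
#' partitions before comparison; set `keep_unassigned = TRUE` to treat
#' them as a cluster of their own.
#'
#' @param p1,p2 `nm_partition` objects, or named integer assignment
#'   vectors.
#' @param keep_unassigned keep module-0 genes as a cluster.
#' @return the ARI, a real number <= 1 (1 for identical partitions, ~0 at
#'   chance agreement).
#' @export
partition_ari <- function(p1, p2, keep_unassigned = FALSE) {
  a1 <- if (inherits(p1, "nm_partition")) p1$assignment else p1
  a2 <- if (inherits(p2, "nm_partition")) p2$assignment else p2
  shared <- intersect(names(a1), names(a2))
  if (!keep_unassigned)
    shared <- shared[a1[shared] != 0L & a2[shared] != 0L]
  if (length(shared) == 0L) stop("no shared assigned genes between partitions")
  x <- a1[shared]; y <- a2[shared]
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  n_pairs <- comb2(length(shared))
  expected <- sum_i * sum_j / n_pairs
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(0)          # e.g. both single-cluster
  (sum_ij - expected) / (max_index - expected)
}

#' Adversarial module pairs
#'
#' Pairs of discriminating modules with opposite directions that
#' correspond to a single module of the topology-only (unit-weight)
#' partition: both members must have that unweighted module as their
#' best Jaccard match, and both overlaps must be significant by a
#' one-sided hypergeometric test under BH control.
#'
#' @param weighted_partition `nm_partition` from the expression-weighted
#'   run.
#' @param unweighted_partition `nm_partition` from the same pipeline with
#'   all edge weights forced to 1 (see `unit_weights` in
#'   [detect_modules()]).
#' @param calls direction calls for the weighted partition from
#'   [call_direction()].
#' @param alpha BH threshold on the overlap tests (default 0.05).
#' @return data.frame with columns `module_mature`, `module_immature`,
#'   `parent_module`, `jaccard_mature`, `jaccard_immature`,
#'   `q_overlap_mature`, `q_overlap_immature`; zero rows when no pair
#'   qualifies.
#' @export
adversarial_pairs <- function(weighted_partition, unweighted_partition, calls,
                              alpha = 0.05) {
  stopifnot(inherits(weighted_partition, "nm_partition"),
            inherits(unweighted_partition, "nm_partition"))
  universe <- union(names(weighted_partition$assignment),
                    names(unweighted_partition$assignment))
  N <- length(universe)
  disc <- calls[calls$direction != "none", , drop = FALSE]
  empty <- data.frame(module_mature = integer(0), module_immature = integer(0),
                      parent_module = integer(0), jaccard_mature = numeric(0),
                      jaccard_immature = numeric(0), q_overlap_mature = numeric(0),
                      q_overlap_immature = numeric(0))
  if (nrow(disc) < 2L || length(unweighted_partition$modules) == 0L) return(empty)
  # best unweighted parent per discriminating module, plus overlap p
  best <- lapply(seq_len(nrow(disc)), function(i) {
    genes <- weighted_partition$modules[[as.character(disc$module[i])]]
    jac <- vapply(unweighted_partition$modules, function(pg) {
      length(intersect(genes, pg)) / length(union(genes, pg))
    }, 0)
    parent_id <- names(jac)[which.max(jac)]
    pg <- unweighted_partition$modules[[parent_id]]
    ov <- length(intersect(genes, pg))
    p <- stats::phyper(ov - 1L, length(pg), N - length(pg), length(genes),
                       lower.tail = FALSE)
    list(module = disc$module[i], direction = as.character(disc$direction[i]),
         parent = as.integer(parent_id), jaccard = max(jac), p = p)
  })
  q <- stats::p.adjust(vapply(best, `[[`, 0, "p"), method = "BH")
  pairs <- list()
  for (i in seq_along(best)) for (j in seq_along(best)) {
    bi <- best[[i]]; bj <- best[[j]]
    if (bi$direction == "mature-high" && bj$direction == "immature-high" &&
        bi$parent == bj$parent && q[i] < alpha && q[j] < alpha) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        module_mature = bi$module, module_immature = bj$module,
        parent_module = bi$parent, jaccard_mature = bi$jaccard,
        jaccard_immature = bj$jaccard, q_overlap_mature = q[i],
        q_overlap_immature = q[j])
    }
  }
  if (length(pairs) == 0L) return(empty)
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' Neuron specificity of discriminating modules
#'
#' Per gene, the neuron enrichment score (NES) is the Pearson correlation
#' between its expression across a purified-cell-type panel and the
#' binary indicator of the target cell type. The neuron specificity index
#' (NSI) of a module is its mean member NES minus the mean NES over genes
#' of non-discriminating modules.
#'
#' @param partition an `nm_partition`.
#' @param calls direction calls from [call_direction()].
#' @param panel genes x samples matrix of cell-type reference expression
#'   (or an `nm_expression`; labels are ignored).
#' @param type_labels character vector of cell types, one per panel
#'   column.
#' @param target_type the cell type defining the indicator (e.g.
#'   `"neuron"`).
#' @return list with `nes` (named per-gene vector) and `nsi` (data.frame
#'   `module`, `direction`, `nsi` over discriminating modules).
#' @export
neuron_specificity <- function(partition, calls, panel, type_labels,
                               target_type = "neuron") {
  m <- if (inherits(panel, "nm_expression")) panel$matrix else as.matrix(panel)
  if (length(type_labels) != ncol(m)) stop("one type label per panel column required")
  if (!target_type %in% type_labels) stop("target type absent from the panel")
  if (length(unique(type_labels)) < 2L) stop("panel needs at least 2 cell types")
  ind <- as.numeric(type_labels == target_type)
  sds <- apply(m, 1L, stats::sd)
  nes <- rep(0, nrow(m))
  ok <- sds > 0
  if (any(!ok)) warning(sprintf("%d zero-variance gene(s): NES set to 0", sum(!ok)))
  nes[ok] <- as.vector(stats::cor(t(m[ok, , drop = FALSE]), ind))
  names(nes) <- rownames(m)
  nondisc <- calls$module[calls$direction == "none"]
  bg_genes <- intersect(unlist(partition$modules[as.character(nondisc)],
                               use.names = FALSE), names(nes))
  if (length(bg_genes) == 0L) stop("no genes in non-discriminating modules with NES")
  bg <- mean(nes[bg_genes])
  disc <- calls[calls$direction != "none", , drop = FALSE]
  nsi <- vapply(disc$module, function(id) {
    g <- intersect(partition$modules[[as.character(id)]], names(nes))
    mean(nes[g]) - bg
  }, 0)
  list(nes = nes,
       nsi = data.frame(module = disc$module,
                        direction = as.character(disc$direction),
                        nsi = nsi, row.names = NULL))
}

#' Gene-set enrichment of a module by Fisher's exact test
#'
#' One-sided (greater) Fisher's exact test of each gene set against the
#' module within the given universe, BH-corrected across the sets of the
#' collection. Sets disjoint from the universe are skipped with a
#' warning.
#'
#' @param module_genes character vector of module member genes.
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param universe gene universe (must contain `module_genes`; typically
#'   all network genes).
#' @return data.frame per set: `set`, `n_overlap`, `n_set`, `odds_ratio`,
#'   `p`, `q_bh`, sorted by p.
#' @export
geneset_enrichment <- function(module_genes, collection, universe) {
  if (length(module_genes) == 0L) stop("empty module")
  if (!all(module_genes %in% universe)) stop("module genes must lie in the universe")
  sets <- lapply(collection, intersect, y = universe)
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty)) {
    warning(sprintf("skipped %d set(s) disjoint from the universe", sum(empty)))
    sets <- sets[!empty]
  }
  if (length(sets) == 0L) stop("no gene set overlaps the universe")
  N <- length(universe); n_mod <- length(module_genes)
  rows <- lapply(names(sets), function(nm) {
    set <- sets[[nm]]
    ov <- length(intersect(module_genes, set))
    tab <- matrix(c(ov, length(set) - ov,
                    n_mod - ov, N - length(set) - n_mod + ov), nrow = 2L)
    ft <- stats::fisher.test(tab, alternative = "greater")
    data.frame(set = nm, n_overlap = ov, n_set = length(set),
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Module signature term
#'
#' The module-specific representative set: among sets enriched in the
#' module (BH < `alpha`), annotated to at least half of the module's
#' genes, and enriched in no other module, the one covering the most
#' module genes (lexicographic tie-break). Returns `NA` when no set
#' qualifies.
#'
#' @param partition an `nm_partition`.
#' @param collection named list of gene sets.
#' @param universe gene universe for the enrichment tests.
#' @param alpha BH threshold (default 0.05).
#' @param modules module ids to report (default: all modules of the
#'   partition).
#' @return data.frame `module`, `signature`, `coverage` (fraction of
#'   module genes annotated; `NA` when none qualifies).
#' @export
signature_term <- function(partition, collection, universe, alpha = 0.05,
                           modules = NULL) {
  stopifnot(inherits(partition, "nm_partition"))
  ids <- if (is.null(modules)) names(partition$modules) else as.character(modules)
  enr <- lapply(names(partition$modules), function(id)
    suppressWarnings(geneset_enrichment(partition$modules[[id]], collection, universe)))
  names(enr) <- names(partition$modules)
  enriched_sets <- lapply(enr, function(e) e$set[e$q_bh < alpha])
  rows <- lapply(ids, function(id) {
    genes <- partition$modules[[id]]
    cand <- enriched_sets[[id]]
    # module-specific: enriched nowhere else
    others <- unlist(enriched_sets[setdiff(names(enriched_sets), id)],
                     use.names = FALSE)
    cand <- setdiff(cand, others)
    cov <- vapply(cand, function(nm)
      length(intersect(genes, collection[[nm]])) / length(genes), 0)
    cand <- cand[cov >= 0.5]; cov <- cov[cov >= 0.5]
    if (length(cand) == 0L)
      return(data.frame(module = as.integer(id), signature = NA_character_,
                        coverage = NA_real_))
    best <- order(-cov, cand)[1L]
    data.frame(module = as.integer(id), signature = cand[best],
               coverage = cov[best])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
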