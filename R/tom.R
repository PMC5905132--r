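#' Topological overlap matrix of a weighted network
#'
#' `TOM_ij = (a_ij + sum_{u != i,j} a_iu a_uj) / (min(k_i, k_j) + 1 - a_ij)`
#' with weighted connectivity `k_i = sum_u a_iu`. The diagonal is set to 1
#' (self-overlap). With all weights in \[0, 1\] every entry lies in
#' \[0, 1\].
#'
#' @param net a weighted [nm_network] (an unweighted network is treated as
#'   all-1 weights).
#' @return symmetric node x node matrix of class `matrix` with unit
#'   diagonal.
#' @export
compute_tom <- function(net) {
  A <- if (inherits(net, "nm_network")) nm_adjacency(net, weighted = TRUE) else as.matrix(net)
  if (any(A < 0)) stop("negative edge weight")
  if (any(A > 1)) stop("edge weights must lie in [0, 1]")
  diag(A) <- 0
  k <- rowSums(A)
  # (A %*% A)[i, j] = sum_u a_iu a_uj; the u = i and u = j terms vanish
  # because the diagonal of A is zero
  shared <- A %*% A
  num <- A + shared
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Adaptive dendrogram cut
#'
#' Dynamic cutting of a dissimilarity dendrogram at a data-chosen height.
#' If the whole tree is tight (root merge height within `min_gap` of the
#' mean merge height) it is one cluster. Otherwise every midpoint between
#' consecutive distinct merge heights below the top merge is scored by
#' the number of branches of at least `min_size` leaves obtained when the
#' tree is cut there, and the cut maximising that count is used (lowest
#' such cut on ties, which keeps modules free of loosely attached
#' leaves).
#' Leaves outside any surviving branch are unassigned (cluster 0). The
#' procedure adapts the cut to the dissimilarity scale of the dendrogram
#' instead of relying on a fixed cut height, and never reports a cluster
#' smaller than `min_size`.
#'
#' @param hc an [stats::hclust] object on a dissimilarity.
#' @param min_size minimal cluster size.
#' @param min_gap tightness threshold deciding whether the whole tree is
#'   a single cluster (default 0.1 on the 1 - TOM dissimilarity scale).
#' @return integer vector of cluster ids (0 = unassigned) named by the
#'   dendrogram labels, with clusters numbered by decreasing size.
#' @export
cut_dendrogram_adaptive <- function(hc, min_size = 20L, min_gap = 0.1) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$order)
  labels <- if (is.null(hc$labels)) as.character(seq_len(n)) else hc$labels
  none <- stats::setNames(integer(n), labels)
  if (n < min_size) return(none)
  h <- hc$height
  if (max(h) - mean(h) < min_gap) {            # tight tree: one module
    return(stats::setNames(rep(1L, n), labels))
  }
  uh <- sort(unique(h))
  if (length(uh) < 2L) return(none)
  cuts <- (uh[-length(uh)] + uh[-1L]) / 2      # strictly below the top merge
  best_cut <- NA_real_; best_count <- 0L
  for (x in cuts) {
    sizes <- tabulate(stats::cutree(hc, h = x))
    cnt <- sum(sizes >= min_size)
    if (cnt > best_count) { best_count <- cnt; best_cut <- x }
  }
  if (best_count == 0L) return(none)
  cl <- stats::cutree(hc, h = best_cut)
  sizes <- tabulate(cl)
  keep <- which(sizes >= min_size)
  assign <- integer(n)
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  for (i in seq_along(ord)) assign[cl == ord[i]] <- i
  stats::setNames(assign, labels)
}

#' Partition genes into modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `d = 1 - TOM`, followed by the adaptive dendrogram cut with a minimal
#' module size. Genes in no surviving branch are unassigned (module 0).
#'
#' @param tom symmetric TOM from [compute_tom()].
#' @param min_size minimal module size (study default 20).
#' @param min_gap see [cut_dendrogram_adaptive()].
#' @return an `nm_partition`: list with `assignment` (named integer
#'   vector, 0 = unassigned), `modules` (list of member vectors named by
#'   module id) and `min_size`.
#' @export
cluster_modules <- function(tom, min_size = 20L, min_gap = 0.1) {
  if (min_size < 2L) stop("min_size must be >= 2")
  n <- nrow(tom)
  if (n < min_size) {
    warning("fewer nodes than min_size: all genes unassigned")
    return(nm_partition(stats::setNames(integer(n), rownames(tom)), min_size))
  }
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  nm_partition(cut_dendrogram_adaptive(hc, min_size, min_gap), min_size)
}

#' @rdname cluster_modules
#' @param assignment named integer vector of module ids (0 = unassigned).
#' @export
nm_partition <- function(assignment, min_size = 2L) {
  assignment <- stats::setNames(as.integer(assignment), names(assignment))
  ids <- sort(setdiff(unique(assignment), 0L))
  modules <- lapply(ids, function(i) names(assignment)[assignment == i])
  names(modules) <- as.character(ids)
  structure(list(assignment = assignment, modules = modules,
                 min_size = as.integer(min_size)), class = "nm_partition")
}

#' @export
print.nm_partition <- function(x, ...) {
  sizes <- lengths(x$modules)
  cat(sprintf("nm_partition: %d modules over %d genes (%d unassigned)\n",
              length(sizes), length(x$assignment), sum(x$assignment == 0L)))
  if (length(sizes))
    cat(sprintf("  sizes: min %d, median %g, max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' End-to-end module detection
#'
#' Composes network restriction to scored genes, insulated heat diffusion,
#' concordance edge weighting, TOM computation and the adaptive dendrogram
#' cut.
#'
#' @param net an [nm_network].
#' @param scores data.frame with `gene` and `s` columns (see
#'   [score_expression()]). Network nodes without a score are dropped.
#' @inheritParams diffusion_matrix
#' @inheritParams cluster_modules
#' @param unit_weights force all edge weights to 1 (module detection from
#'   topology alone, used for adversarial-pair comparison).
#' @return list with `partition`, `diffusion` (an `nm_diffusion`), `tom`
#'   and `params`.
#' @export
detect_modules <- function(net, scores, beta = 0.55, min_size = 20L,
                           min_gap = 0.1, unit_weights = FALSE) {
  if (is.null(scores) || nrow(scores) == 0L) stop("empty score vector")
  keep <- intersect(net$nodes, scores$gene)
  if (length(keep) == 0L) stop("no network node has a score")
  if (length(keep) < length(net$nodes)) {
    ed <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, , drop = FALSE]
    net <- structure(list(nodes = sort(keep), edges = ed), class = "nm_network")
  }
  diff <- diffuse_scores(net, scores[scores$gene %in% keep, , drop = FALSE], beta)
  wnet <- diff$network
  if (unit_weights) wnet$edges$weight <- rep(1, nrow(wnet$edges))
  tom <- compute_tom(wnet)
  partition <- cluster_modules(tom, min_size = min_size, min_gap = min_gap)
  list(partition = partition, diffusion = diff, tom = tom,
       params = list(beta = beta, min_size = min_size, min_gap = min_gap,
                     unit_weights = unit_weights))
}
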