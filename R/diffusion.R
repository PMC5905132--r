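#' Column-stochastic normalized adjacency matrix
#'
#' The random-walk matrix `W = A D^-1` (HotNet2 convention), where `A` is
#' the unweighted 0/1 adjacency and `D` the diagonal degree matrix.
#' Columns of isolated nodes are all zero.
#'
#' @param net an [nm_network].
#' @return node x node matrix whose non-isolated columns sum to 1.
#' @export
normalize_adjacency <- function(net) {
  A <- nm_adjacency(net, weighted = FALSE)
  if (nrow(A) == 0L) stop("empty network")
  deg <- colSums(A)
  W <- sweep(A, 2L, pmax(deg, 1), "/")
  W[, deg == 0] <- 0
  W
}

#' Insulated heat-diffusion matrix
#'
#' `F = beta * (I - (1 - beta) W)^-1`, the equilibrium exchange matrix of
#' an insulated diffusion process in which every node retains a fraction
#' `beta` of incoming heat. Computed by a dense linear solve of
#' `(I - (1 - beta) W) X = beta I`, which equals the explicit inverse to
#' numerical precision.
#'
#' @param W column-stochastic normalized adjacency from
#'   [normalize_adjacency()].
#' @param beta insulating parameter in (0, 1]; the study default is 0.55.
#' @return dense diffusion matrix with the dimnames of `W`.
#' @export
diffusion_matrix <- function(W, beta = 0.55) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
    stop("beta must lie in (0, 1]")
  n <- nrow(W)
  Fm <- solve(diag(n) - (1 - beta) * W, diag(beta, n))
  dimnames(Fm) <- dimnames(W)
  Fm
}

#' Smooth node scores through the diffusion matrix
#'
#' `shat = F s`. On a graph without isolated nodes the total heat is
#' conserved: `sum(shat) == sum(s)`. An isolated node keeps `beta * s_i`.
#'
#' @param Fm diffusion matrix from [diffusion_matrix()].
#' @param s named numeric score vector; names must cover the rows of `Fm`.
#' @return named numeric vector of smoothed scores.
#' @export
smooth_scores <- function(Fm, s) {
  if (!is.null(names(s)) && !is.null(rownames(Fm))) {
    missing <- setdiff(rownames(Fm), names(s))
    if (length(missing)) stop("scores missing for node(s): ",
                              paste(utils::head(missing, 5L), collapse = ", "))
    s <- s[rownames(Fm)]
  }
  if (length(s) != nrow(Fm)) stop("score vector length does not match the network")
  if (anyNA(s)) stop("NaN/NA score for gene(s): ",
                     paste(utils::head(names(s)[is.na(s)], 5L), collapse = ", "))
  drop(Fm %*% s)
}

#' Concordance edge weights from smoothed scores
#'
#' Assigns each edge `(i, j)` the weight
#' `a_ij = 1 - |shat_i - shat_j| / (2 * max(|shat_i|, |shat_j|))`,
#' which lies in \[0, 1\]: 1 for identical smoothed scores (including the
#' 0/0 case, defined as 1), 0 for exactly opposite scores.
#'
#' @param net an [nm_network].
#' @param shat named smoothed-score vector covering all nodes.
#' @return the network with a `weight` column on its edges.
#' @export
edge_weights <- function(net, shat) {
  stopifnot(inherits(net, "nm_network"))
  missing <- setdiff(net$nodes, names(shat))
  if (length(missing)) stop("smoothed scores missing for node(s): ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  si <- shat[net$edges$from]; sj <- shat[net$edges$to]
  mx <- pmax(abs(si), abs(sj))
  a <- ifelse(mx == 0, 1, 1 - abs(si - sj) / (2 * mx))
  set_edge_weights(net, a)
}

#' Run the full smoothing stage
#'
#' Composes [normalize_adjacency()], [diffusion_matrix()],
#' [smooth_scores()] and [edge_weights()].
#'
#' @param net an [nm_network].
#' @param scores data.frame from [score_expression()] (or any frame with
#'   `gene` and `s` columns) covering all network nodes.
#' @inheritParams diffusion_matrix
#' @return list with `network` (weighted), `shat` (named vector), `beta`
#'   and `F` (diffusion matrix); class `nm_diffusion`.
#' @export
diffuse_scores <- function(net, scores, beta = 0.55) {
  s <- stats::setNames(scores$s, scores$gene)
  W <- normalize_adjacency(net)
  Fm <- diffusion_matrix(W, beta)
  shat <- smooth_scores(Fm, s)
  structure(list(network = edge_weights(net, shat), shat = shat,
                 beta = beta, F = Fm), class = "nm_diffusion")
}
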