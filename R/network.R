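#' Construct a network object
#'
#' A network is an undirected simple graph over gene identifiers, with
#' optional per-edge weights in \[0, 1\]. Self-loops are dropped and
#' duplicate edges collapsed (keeping the first weight seen). Node order is
#' deterministic (lexicographic).
#'
#' @param edges two-column character matrix/data.frame of edge endpoints,
#'   optionally with a third numeric `weight` column.
#' @param nodes optional character vector of node identifiers; defaults to
#'   the identifiers appearing in `edges`. Extra identifiers become
#'   isolated nodes.
#' @return an object of class `nm_network`: a list with elements `nodes`
#'   (sorted character vector) and `edges` (data.frame with columns
#'   `from`, `to` and, when weighted, `weight`; `from < to` lexicographic).
#' @export
nm_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edges must have at least two columns")
  weighted <- ncol(edges) >= 3L
  ed <- data.frame(from = as.character(edges[[1L]]),
                   to   = as.character(edges[[2L]]),
                   stringsAsFactors = FALSE)
  if (weighted) {
    w <- as.numeric(edges[[3L]])
    if (anyNA(w)) stop("non-numeric edge weight")
    if (any(w < 0 | w > 1)) stop("edge weights must lie in [0, 1]")
    ed$weight <- w
  }
  loops <- ed$from == ed$to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    ed <- ed[!loops, , drop = FALSE]
  }
  # canonical orientation, then collapse duplicates
  flip <- ed$from > ed$to
  tmp <- ed$from[flip]; ed$from[flip] <- ed$to[flip]; ed$to[flip] <- tmp
  key <- paste(ed$from, ed$to, sep = "\r")
  ed <- ed[!duplicated(key), , drop = FALSE]
  all_nodes <- sort(unique(c(ed$from, ed$to, as.character(nodes))))
  if (length(all_nodes) == 0L) stop("empty network")
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(nodes = all_nodes, edges = ed), class = "nm_network")
}

#' @export
print.nm_network <- function(x, ...) {
  cat(sprintf("nm_network: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (is_weighted(x)) " (weighted)" else ""))
  invisible(x)
}

is_weighted <- function(net) "weight" %in% names(net$edges)

n_nodes <- function(net) length(net$nodes)

#' Adjacency matrix of a network
#'
#' @param net an `nm_network`.
#' @param weighted use edge weights when present (missing edges are 0);
#'   otherwise 0/1 adjacency.
#' @param sparse return a sparse `Matrix::dsCMatrix`.
#' @return symmetric node x node matrix with zero diagonal, dimnames set to
#'   node identifiers.
#' @export
nm_adjacency <- function(net, weighted = TRUE, sparse = FALSE) {
  stopifnot(inherits(net, "nm_network"))
  n <- n_nodes(net)
  i <- match(net$edges$from, net$nodes)
  j <- match(net$edges$to, net$nodes)
  w <- if (weighted && is_weighted(net)) net$edges$weight else rep(1, nrow(net$edges))
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n), dimnames = list(net$nodes, net$nodes))
  if (sparse) A else as.matrix(A)
}

#' Assign edge weights from a named vector keyed by "from|to"
#' @noRd
set_edge_weights <- function(net, w) {
  stopifnot(length(w) == nrow(net$edges))
  net$edges$weight <- as.numeric(w)
  net
}
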