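# Small builders shared across the test files. Everything is generated in
# code; no fixture files.

# complete graph over the given node names, optionally weighted
clique_edges <- function(nodes, weight = NULL) {
  e <- as.data.frame(t(utils::combn(nodes, 2)), stringsAsFactors = FALSE)
  names(e) <- c("from", "to")
  if (!is.null(weight)) e$weight <- weight
  e
}

two_clique_network <- function(n = 25L, weight = 1) {
  a <- sprintf("a%02d", seq_len(n)); b <- sprintf("b%02d", seq_len(n))
  nm_network(rbind(clique_edges(a, weight), clique_edges(b, weight)))
}

# tiny labeled expression matrix: one row per supplied gene vector entry
toy_expression <- function(mat, n1 = NULL) {
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  if (is.null(n1)) n1 <- ncol(mat) %/% 2
  lab <- stats::setNames(rep(c("mature", "immature"),
                             c(n1, ncol(mat) - n1)), colnames(mat))
  nm_expression(mat, lab)
}

# Erdos-Renyi style random connected-ish network with random [0,1] weights
random_weighted_network <- function(n, p = 0.3, weighted = TRUE) {
  nodes <- sprintf("n%03d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  # guarantee no isolated node by adding a ring
  ring <- cbind(nodes, c(nodes[-1L], nodes[1L]))
  ed <- data.frame(from = c(pairs[1L, keep], ring[, 1L]),
                   to = c(pairs[2L, keep], ring[, 2L]))
  if (weighted) ed$weight <- stats::runif(nrow(ed))
  nm_network(ed)
}

# naive O(n^3) TOM used as an independent oracle
tom_oracle <- function(A) {
  diag(A) <- 0
  n <- nrow(A)
  k <- rowSums(A)
  out <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- 0
    for (u in seq_len(n)) if (u != i && u != j) shared <- shared + A[i, u] * A[u, j]
    out[i, j] <- (A[i, j] + shared) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  dimnames(out) <- dimnames(A)
  out
}

# brute-force pair-counting adjusted Rand index oracle
ari_oracle <- function(x, y) {
  n <- length(x)
  n11 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sx <- x[i] == x[j]; sy <- y[i] == y[j]
    if (sx && sy) n11 <- n11 + 1
    else if (sx) n10 <- n10 + 1
    else if (sy) n01 <- n01 + 1
  }
  total <- n * (n - 1) / 2
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) return(0)
  (n11 - expected) / (max_index - expected)
}

# all set partitions of seq_len(n) as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- labels; return(invisible(NULL)) }
    for (v in seq_len(k + 1L)) rec(c(labels, v), max(k, v))
    invisible(NULL)
  }
  rec(integer(0), 0L)
  out
}
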