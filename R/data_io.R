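#' Read an undirected network from disk
#'
#' Supported formats: `edgelist-tsv` (two tab- or whitespace-separated node
#' columns, optional third weight column, optional header, `#` comments)
#' and `sif` (node \\t relation \\t node, one or more targets per line).
#' Self-loops are dropped with a warning and duplicate edges collapsed.
#'
#' @param path file path.
#' @param format one of `"edgelist-tsv"`, `"sif"`.
#' @return an [nm_network].
#' @export
read_network <- function(path, format = c("edgelist-tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty network: ", path)
  toks <- strsplit(trimws(lines), "[\t ]+")
  if (format == "edgelist-tsv") {
    bad <- which(vapply(toks, length, 1L) < 2L)
    if (length(bad)) stop(sprintf("malformed line %d in %s: need two node columns",
                                  bad[1L], path))
    from <- vapply(toks, `[`, "", 1L)
    to   <- vapply(toks, `[`, "", 2L)
    w    <- vapply(toks, function(t) if (length(t) >= 3L) t[3L] else NA_character_, "")
    # tolerate a single header line (non-numeric weight column or the
    # classic from/to header words)
    if (!all(is.na(w))) {
      wn <- suppressWarnings(as.numeric(w))
      if (is.na(wn[1L]) && !is.na(w[1L]) && all(!is.na(wn[-1L]))) {
        from <- from[-1L]; to <- to[-1L]; wn <- wn[-1L]
      }
      if (all(!is.na(wn))) return(nm_network(data.frame(from, to, weight = wn)))
      if (!all(is.na(wn))) stop("malformed weight column in ", path)
    }
    if (tolower(from[1L]) %in% c("from", "source", "node1", "gene1")) {
      from <- from[-1L]; to <- to[-1L]
    }
    if (length(from) == 0L) stop("empty network: ", path)
    nm_network(data.frame(from, to))
  } else {
    bad <- which(vapply(toks, length, 1L) == 2L)
    if (length(bad)) stop(sprintf("malformed SIF line %d in %s", bad[1L], path))
    from <- character(0); to <- character(0); nodes <- character(0)
    for (t in toks) {
      if (length(t) == 1L) { nodes <- c(nodes, t) ; next }
      from <- c(from, rep(t[1L], length(t) - 2L))
      to   <- c(to, t[-(1:2)])
    }
    if (length(from) == 0L && length(nodes) == 0L) stop("empty network: ", path)
    if (length(from) == 0L) return(structure(list(nodes = sort(unique(nodes)),
      edges = data.frame(from = character(0), to = character(0))), class = "nm_network"))
    nm_network(data.frame(from, to), nodes = nodes)
  }
}

#' Write a network as a (weighted) edge-list TSV
#'
#' @param net an [nm_network].
#' @param path output path.
#' @param header optional character vector of `#`-prefixed comment lines.
#' @export
write_network <- function(net, path, header = NULL) {
  stopifnot(inherits(net, "nm_network"))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(net$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # keep isolated nodes through a round-trip
  iso <- setdiff(net$nodes, c(net$edges$from, net$edges$to))
  if (length(iso)) writeLines(paste0("# isolated\t", iso), con)
  invisible(path)
}

#' Read a genes x samples expression matrix with sample labels
#'
#' TSV format: header row of sample identifiers, first column gene
#' identifiers. MatrixMarket format: coordinate `.mtx` file plus
#' `genes.txt` (row names) and `barcodes.txt` (column names) in the same
#' directory (or given explicitly).
#'
#' @param path expression file path.
#' @param labels_path two-column TSV mapping sample -> class label, or a
#'   named character vector of labels.
#' @param format `"tsv"` or `"mtx"`.
#' @param class1,class0 label values denoting the positive (mature) and
#'   negative (immature) class. Defaults `"mature"` / `"immature"`.
#' @param genes_path,barcodes_path row/column name files for `format = "mtx"`.
#' @return an object of class `nm_expression`: list with `matrix`
#'   (genes x samples, nonnegative), `labels` (factor with levels
#'   `c(class0, class1)` named by sample).
#' @export
read_expression <- function(path, labels_path, format = c("tsv", "mtx"),
                            class1 = "mature", class0 = "immature",
                            genes_path = NULL, barcodes_path = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#")
    genes <- as.character(tab[[1L]])
    dup <- genes[duplicated(genes)]
    if (length(dup)) stop("duplicated gene row(s): ", paste(unique(dup), collapse = ", "))
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
  } else {
    dir <- dirname(path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.txt")
    if (is.null(barcodes_path)) barcodes_path <- file.path(dir, "barcodes.txt")
    mm <- Matrix::readMM(path)
    genes <- readLines(genes_path); cells <- readLines(barcodes_path)
    if (nrow(mm) != length(genes) || ncol(mm) != length(cells))
      stop("MTX dimensions do not match genes/barcodes files")
    m <- as.matrix(mm)
    dimnames(m) <- list(genes, cells)
  }
  labels <- read_labels(labels_path)
  nm_expression(m, labels, class1 = class1, class0 = class0)
}

#' @rdname read_expression
#' @param labels a sample -> class mapping (named vector or 2-col data.frame).
#' @param matrix genes x samples numeric matrix with dimnames.
#' @export
nm_expression <- function(matrix, labels, class1 = "mature", class0 = "immature") {
  if (is.data.frame(labels)) labels <- stats::setNames(as.character(labels[[2L]]),
                                                       as.character(labels[[1L]]))
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicated gene row(s): ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]), collapse = ", "))
  if (!all(is.finite(matrix))) stop("expression matrix has non-finite entries")
  if (any(matrix < 0)) stop("expression matrix has negative entries")
  missing <- setdiff(colnames(matrix), names(labels))
  if (length(missing)) stop("samples without labels: ", paste(missing, collapse = ", "))
  lab <- as.character(labels[colnames(matrix)])
  bad <- setdiff(unique(lab), c(class0, class1))
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  lab <- factor(lab, levels = c(class0, class1))
  if (any(table(lab) == 0L)) stop("both classes must be nonempty")
  structure(list(matrix = matrix, labels = stats::setNames(lab, colnames(matrix))),
            class = "nm_expression")
}

#' @export
print.nm_expression <- function(x, ...) {
  cat(sprintf("nm_expression: %d genes x %d samples (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)), collapse = ", ")))
  invisible(x)
}

read_labels <- function(labels) {
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    tab <- utils::read.table(labels, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
    if (tolower(tab[1L, 1L]) %in% c("sample", "cell", "id"))
      tab <- tab[-1L, , drop = FALSE]
    stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
  } else if (!is.null(names(labels))) {
    labels
  } else stop("labels must be a TSV path or a named vector")
}

#' Restrict a network to expressed genes
#'
#' Removes nodes that have no expression row, or whose expression exceeds
#' `min_expr` in fewer than `min_frac` of samples, together with their
#' edges. Isolated nodes that pass the filter are retained.
#'
#' @param net an [nm_network].
#' @param expr an `nm_expression`.
#' @param min_expr expression threshold a sample must exceed to count as
#'   detected (default 0).
#' @param min_frac minimal fraction of samples with detected expression
#'   (default 0: any single nonzero sample keeps the gene).
#' @return filtered [nm_network].
#' @export
restrict_to_expressed <- function(net, expr, min_expr = 0, min_frac = 0) {
  stopifnot(inherits(net, "nm_network"), inherits(expr, "nm_expression"))
  present <- intersect(net$nodes, rownames(expr$matrix))
  frac <- rowMeans(expr$matrix[present, , drop = FALSE] > min_expr)
  keep <- present[frac >= min_frac & frac > 0]
  if (length(keep) == 0L) stop("no expressed network genes remain")
  ed <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(nodes = sort(keep), edges = ed), class = "nm_network")
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @param universe optional gene universe; sets are intersected with it and
#'   emptied sets dropped with a warning.
#' @return named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(toks, length, 1L) < 3L)
  if (length(bad)) stop(sprintf("malformed GMT line %d: need name, description, genes",
                                bad[1L]))
  sets <- lapply(toks, function(t) unique(t[-(1:2)]))
  names(sets) <- vapply(toks, `[`, "", 1L)
  desc <- stats::setNames(vapply(toks, `[`, "", 2L), names(sets))
  if (!is.null(universe)) {
    sets <- lapply(sets, intersect, y = universe)
    empty <- vapply(sets, length, 1L) == 0L
    if (any(empty)) {
      warning(sprintf("dropped %d set(s) disjoint from the universe", sum(empty)))
      sets <- sets[!empty]; desc <- desc[!empty]
    }
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Write a TSV with provenance header comments
#' @noRd
write_tsv_stamped <- function(df, path, seed = NULL, command = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  ver <- as.character(utils::packageVersion("netmature"))
  writeLines(sprintf("# netmature %s", ver), con)
  if (!is.null(command)) writeLines(paste0("# command: ", command), con)
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
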