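#' Per-class mean expression
#'
#' Arithmetic mean FPKM per gene within each sample class.
#'
#' @param expr an `nm_expression`.
#' @return data.frame with columns `gene`, `mean1` (class1, "mature") and
#'   `mean0` (class0, "immature").
#' @export
group_means <- function(expr) {
  stopifnot(inherits(expr, "nm_expression"))
  cls1 <- expr$labels == levels(expr$labels)[2L]
  if (!any(cls1) || all(cls1)) stop("both classes need at least one sample")
  data.frame(gene = rownames(expr$matrix),
             mean1 = rowMeans(expr$matrix[, cls1, drop = FALSE]),
             mean0 = rowMeans(expr$matrix[, !cls1, drop = FALSE]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group one-way ANOVA p-values, vectorised over genes
#'
#' With two groups the one-way ANOVA F statistic equals the squared
#' equal-variance t statistic, so the p-value is computed from
#' F(1, n - 2). Genes with zero between- and within-group variance (all
#' values identical) get p = 1.
#'
#' @param m genes x samples numeric matrix.
#' @param cls1 logical vector marking class-1 samples.
#' @return numeric vector of p-values in (0, 1].
#' @export
row_anova_p <- function(m, cls1) {
  n1 <- sum(cls1); n0 <- sum(!cls1); n <- n1 + n0
  if (n1 < 1L || n0 < 1L) stop("both classes need at least one sample")
  if (n < 3L) stop("need at least 3 samples for a two-group ANOVA")
  m1 <- rowMeans(m[, cls1, drop = FALSE])
  m0 <- rowMeans(m[, !cls1, drop = FALSE])
  ss1 <- rowSums((m[, cls1, drop = FALSE] - m1)^2)
  ss0 <- rowSums((m[, !cls1, drop = FALSE] - m0)^2)
  ss_between <- n1 * n0 / n * (m1 - m0)^2
  ss_within <- ss1 + ss0
  f <- ss_between / (ss_within / (n - 2L))
  p <- stats::pf(f, 1L, n - 2L, lower.tail = FALSE)
  # all identical: 0/0 -> NaN; no evidence against the null
  p[ss_between == 0 & ss_within == 0] <- 1
  # perfect separation with zero within-group variance: F -> Inf
  p[ss_between > 0 & ss_within == 0] <- 0
  p
}

#' Expression alteration score
#'
#' The signed differential-expression magnitude
#' `s = log2(f) * (-log10(p))` with fold change
#' `f = (mean1 + pseudocount) / (mean0 + pseudocount)`. Positive scores
#' mean higher expression in the mature class.
#'
#' @param mean1,mean0 per-gene class means (FPKM scale).
#' @param p per-gene ANOVA p-values in (0, 1].
#' @param pseudocount added to both means before the ratio (default 1
#'   FPKM); must be positive.
#' @param p_floor lower bound applied to p before the log so underflowed
#'   p-values keep s finite (default 1e-300).
#' @return data.frame with columns `f` and `s`.
#' @export
alteration_score <- function(mean1, mean0, p, pseudocount = 1, p_floor = 1e-300) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (any(p > 1 | p < 0, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  f <- (mean1 + pseudocount) / (mean0 + pseudocount)
  s <- log2(f) * (-log10(pmax(p, p_floor)))
  data.frame(f = f, s = s)
}

#' Score every gene for expression alteration between classes
#'
#' Composes [group_means()], [row_anova_p()] and [alteration_score()].
#'
#' @inheritParams group_means
#' @inheritParams alteration_score
#' @param log1p run the ANOVA on `log(FPKM + 1)` instead of raw FPKM.
#' @return data.frame with columns `gene`, `mean1`, `mean0`, `f`, `p`, `s`.
#' @export
score_expression <- function(expr, pseudocount = 1, p_floor = 1e-300,
                             log1p = FALSE) {
  gm <- group_means(expr)
  cls1 <- expr$labels == levels(expr$labels)[2L]
  m <- if (log1p) log1p(expr$matrix) else expr$matrix
  p <- row_anova_p(m, cls1)
  sc <- alteration_score(gm$mean1, gm$mean0, p, pseudocount, p_floor)
  data.frame(gene = gm$gene, mean1 = gm$mean1, mean0 = gm$mean0,
             f = sc$f, p = p, s = sc$s, row.names = NULL,
             stringsAsFactors = FALSE)
}
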