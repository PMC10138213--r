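## Gene set enrichment scoring: single-sample (ssGSEA) scores, classic
## GSEA running-sum statistics with a gene-set permutation null, z-scored
## signature scores and signature-signature correlation.

set_members <- function(gene_set) {
  if (inherits(gene_set, "gene_set")) gene_set$members
  else unique(as.character(gene_set))
}

set_label <- function(gene_set) {
  if (inherits(gene_set, "gene_set")) gene_set$name else "gene set"
}

## Stable descending order: ties broken by input position.
rank_descending <- function(x) order(-x)

#' Single-sample gene set enrichment (ssGSEA) score
#'
#' Genes are ranked by expression, descending, ties broken by input
#' order.  Walking the ranked list, the in-set running fraction is
#' weighted by the expression rank raised to `alpha` (the top gene
#' carries rank N, so highly expressed members weigh most), normalized by
#' the summed in-set weights; the out-of-set running fraction steps by
#' `1/(N - |S|)`.  The score is the sum of the running difference over
#' all N positions (an integrated weighted-ECDF difference).  The score
#' depends only on ranks, so it is invariant to monotone transformations
#' of the expression values.
#'
#' @param expr Named numeric vector: per-gene expression for one sample.
#' @param gene_set A [gene_set()] or character vector of members; at
#'   least one member must be present, and the set must not equal the
#'   whole universe.
#' @param alpha Rank-weighting exponent (default 0.75).
#' @return A single numeric score (bounded by N in absolute value).
#' @examples
#' ssgsea_score(c(g1 = 3, g2 = 2, g3 = 1), c("g1"), alpha = 0)  # 1.5
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.75) {
  members <- set_members(gene_set)
  stopifnot(is.numeric(expr), !is.null(names(expr)))
  N <- length(expr)
  ord <- rank_descending(expr)
  inset <- names(expr)[ord] %in% members
  k <- sum(inset)
  if (k == 0L)
    stop("no member of '", set_label(gene_set),
         "' is present in the expression vector", call. = FALSE)
  if (k == N)
    stop("'", set_label(gene_set),
         "' equals the whole gene universe; score undefined",
         call. = FALSE)
  w <- (N - seq_len(N) + 1)^alpha       # expression rank N..1 to alpha
  cdf_in <- cumsum(w * inset) / sum(w * inset)
  cdf_out <- cumsum(!inset) / (N - k)
  sum(cdf_in - cdf_out)
}

#' ssGSEA scores for every sample of an expression matrix
#'
#' @param mat Genes x samples numeric matrix with row and column names.
#' @inheritParams ssgsea_score
#' @return Named numeric vector of per-sample scores.
#' @export
ssgsea_matrix <- function(mat, gene_set, alpha = 0.75) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  apply(mat, 2, function(col)
    ssgsea_score(setNames(col, rownames(mat)), gene_set, alpha))
}

#' Z-score a vector of per-sample signature scores
#'
#' `(x - mean) / SD` with the sample SD (n - 1 denominator), as used when
#' presenting per-sample enrichment scores as z scores.
#'
#' @param scores Numeric vector of length >= 2.
#' @return Z-scored vector (mean 0, SD 1).
#' @export
zscore_signature <- function(scores) {
  if (length(scores) < 2L)
    stop("need >= 2 samples to z-score", call. = FALSE)
  s <- sd(scores)
  if (s == 0)
    stop("constant scores (SD = 0) carry no ordering information",
         call. = FALSE)
  (scores - mean(scores)) / s
}

## Running-sum ES on an already-sorted metric.  inset: logical in sorted
## order; absm: |metric|^weight in sorted order.
es_from_sorted <- function(inset, absm, weight) {
  N <- length(inset)
  k <- sum(inset)
  denom <- sum(absm[inset])
  if (denom == 0) {
    if (weight > 0)
      stop("all in-set metric values are zero; weighted steps undefined",
           call. = FALSE)
    denom <- k
  }
  steps <- ifelse(inset, absm / denom, -1 / (N - k))
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

#' Classic GSEA enrichment score
#'
#' Running-sum statistic over a ranked gene list: in-set positions add
#' `|metric|^weight` normalized by the in-set total; out-of-set positions
#' subtract `1/(N - |S|)`.  The enrichment score (ES) is the running-sum
#' value of maximal absolute deviation from zero, signed.  With
#' `weight = 0` the ES lies in `[-1, 1]`.
#'
#' @param metric Named numeric vector of ranking-metric values (any
#'   order; sorted descending internally, ties stable).
#' @param gene_set A [gene_set()] or character vector; >= 1 member must
#'   be present.
#' @param weight Metric-weighting exponent (default 1).
#' @return The signed ES.
#' @examples
#' gsea_es(c(a = 2, b = 1, c = 1), "a")  # +1
#' @export
gsea_es <- function(metric, gene_set, weight = 1) {
  members <- set_members(gene_set)
  stopifnot(is.numeric(metric), !is.null(names(metric)),
            all(is.finite(metric)))
  ord <- rank_descending(metric)
  inset <- names(metric)[ord] %in% members
  if (!any(inset))
    stop("no member of '", set_label(gene_set),
         "' is present in the ranked list", call. = FALSE)
  if (all(inset))
    stop("'", set_label(gene_set), "' equals the whole ranked list",
         call. = FALSE)
  es_from_sorted(inset, abs(metric[ord])^weight, weight)
}

#' Signal-to-noise ranking metric between two classes
#'
#' `(mu1 - mu2) / (sigma1 + sigma2)` per gene, with each SD floored at
#' `0.2 * |mu|` of its class (and at 0.2 when the mean is 0) to avoid
#' degenerate small-replicate metrics.
#'
#' @param mat Genes x samples matrix.
#' @param groups Two-level factor/character vector over columns; the
#'   first level is the "treatment" class.
#' @return Named numeric metric vector.
#' @export
signal_to_noise <- function(mat, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("'groups' must have exactly two levels", call. = FALSE)
  i1 <- groups == levels(groups)[1]
  i2 <- groups == levels(groups)[2]
  if (sum(i1) < 2L || sum(i2) < 2L)
    stop("both classes need >= 2 samples", call. = FALSE)
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  s1 <- apply(mat[, i1, drop = FALSE], 1, sd)
  s2 <- apply(mat[, i2, drop = FALSE], 1, sd)
  floor_sd <- function(s, m) pmax(s, ifelse(m == 0, 0.2, 0.2 * abs(m)))
  metric <- (m1 - m2) / (floor_sd(s1, m1) + floor_sd(s2, m2))
  setNames(metric, rownames(mat))
}

#' GSEA with a gene-set permutation null
#'
#' Ranks genes by the signal-to-noise metric between the two classes,
#' computes the observed ES for the gene set, and builds the null from
#' `n_perm` random same-size gene sets (gene-set permutation, appropriate
#' for designs with very few samples per class).  The permutation p-value
#' is two-sided on the ES magnitude,
#' `p = (1 + #\{|ES_null| >= |ES|\}) / (n_perm + 1)`, and the NES
#' normalizes the ES by the mean `|ES_null|` of the null scores sharing
#' its sign.
#'
#' @param mat Genes x samples matrix (rownames = gene ids).
#' @param groups Two-level class labels over columns (>= 2 samples each).
#' @param gene_set A [gene_set()] or character vector of members.
#' @param n_perm Number of null sets (>= 10; default 1000).
#' @param weight Metric-weighting exponent passed to the running sum.
#' @param seed Optional integer seed for the null draws.
#' @return A list of class `enrichment_result`: `es`, `nes`, `p_perm`,
#'   `n_perm`, `set_name`, `metric` (named, sorted descending).
#' @export
gsea_permutation <- function(mat, groups, gene_set, n_perm = 1000,
                             weight = 1, seed = NULL) {
  if (n_perm < 10)
    stop("n_perm must be >= 10", call. = FALSE)
  members <- set_members(gene_set)
  universe <- rownames(mat)
  k <- sum(universe %in% members)
  if (k == 0L)
    stop("no member of '", set_label(gene_set),
         "' is present in the matrix", call. = FALSE)
  if (k >= length(universe))
    stop("gene set is not smaller than the universe", call. = FALSE)
  metric <- signal_to_noise(mat, groups)
  ord <- rank_descending(metric)
  sorted_names <- names(metric)[ord]
  absm <- abs(metric[ord])^weight
  inset_obs <- sorted_names %in% members
  es <- es_from_sorted(inset_obs, absm, weight)

  if (!is.null(seed)) set.seed(seed)
  es_null <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(length(sorted_names), k)
    inset <- logical(length(sorted_names))
    inset[idx] <- TRUE
    es_from_sorted(inset, absm, weight)
  }, numeric(1))

  p <- (1 + sum(abs(es_null) >= abs(es))) / (n_perm + 1)
  same_sign <- es_null[sign(es_null) == sign(es)]
  nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
  structure(list(es = es, nes = nes, p_perm = p, n_perm = n_perm,
                 set_name = set_label(gene_set),
                 metric = setNames(metric[ord], sorted_names)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("GSEA: ", x$set_name, "  ES = ", signif(x$es, 4),
      "  NES = ", signif(x$nes, 4), "  p_perm = ", signif(x$p_perm, 4),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Pearson correlation between two signature score vectors
#'
#' @param zA,zB Equal-length (>= 3) numeric vectors, typically z-scored
#'   per-sample signature scores.
#' @return A list: `r` (Pearson coefficient), `p` (two-sided, from the
#'   t transform with n - 2 df), `n`.
#' @export
correlate_signatures <- function(zA, zB) {
  if (length(zA) != length(zB))
    stop("score vectors differ in length", call. = FALSE)
  if (length(zA) < 3L)
    stop("need >= 3 samples to correlate", call. = FALSE)
  if (any(!is.finite(zA)) || any(!is.finite(zB)))
    stop("non-finite score values", call. = FALSE)
  if (sd(zA) == 0 || sd(zB) == 0)
    stop("zero variance in a score vector", call. = FALSE)
  ct <- cor.test(zA, zB, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(zA))
}
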