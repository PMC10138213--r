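## Per-gene differential contrasts and the induced / cooperative
## gene-selection rules.

condition_columns <- function(se, condition) {
  cond <- SummarizedExperiment::colData(se)$condition
  if (is.null(cond))
    stop("expression object lacks a 'condition' column", call. = FALSE)
  idx <- which(cond == condition)
  if (length(idx) == 0L)
    stop("condition '", condition, "' absent from expression data",
         call. = FALSE)
  idx
}

#' Per-gene differential contrast between two conditions
#'
#' For every gene, computes the log2 fold change (treatment mean minus
#' reference mean on the log2 scale), a two-sided pooled-variance
#' two-sample Student t-test p-value (df = n1 + n2 - 2), and the
#' Benjamini-Hochberg adjusted p-value over the full gene universe of
#' the matrix.  The pooled test is used rather than the Welch variant
#' because at very small replicate numbers (2-3 per arm) the
#' Welch-Satterthwaite degrees of freedom collapse toward 2 and the test
#' loses most of its power; replicate arms of the same array experiment
#' are assumed homoscedastic.
#'
#' Degenerate conventions: when both groups have zero variance the test
#' statistic is undefined, so equal means report `p = 1` and unequal means
#' report the smallest positive double (deterministically significant, as
#' required for noiseless fixtures).
#'
#' @param se A `SummarizedExperiment` with assay `"log2"` and `condition`
#'   column data.
#' @param treatment,reference Condition labels; each must have >= 2
#'   replicates.
#' @return A `data.frame` with columns `gene`, `log2fc`, `p`, `q`.
#' @examples
#' cfg <- synth_config(seed = 1, n_genes = 50)
#' se <- generate_expression(cfg, plant_truth(cfg, generate_annotation(cfg)))
#' head(contrast(se, "Combo", "DMSO"))
#' @export
contrast <- function(se, treatment, reference) {
  ti <- condition_columns(se, treatment)
  ri <- condition_columns(se, reference)
  if (length(ti) < 2L || length(ri) < 2L)
    stop("both conditions need >= 2 replicates", call. = FALSE)
  mat <- SummarizedExperiment::assay(se, "log2")
  if (any(!is.finite(mat)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  xt <- mat[, ti, drop = FALSE]
  xr <- mat[, ri, drop = FALSE]
  nt <- length(ti); nr <- length(ri)
  mt <- rowMeans(xt); mr <- rowMeans(xr)
  vt <- rowSums((xt - mt)^2) / (nt - 1)
  vr <- rowSums((xr - mr)^2) / (nr - 1)
  log2fc <- mt - mr
  df <- nt + nr - 2
  sp2 <- ((nt - 1) * vt + (nr - 1) * vr) / df
  se2 <- sp2 * (1 / nt + 1 / nr)
  p <- numeric(nrow(mat))
  degen <- se2 == 0
  ok <- !degen
  tstat <- log2fc[ok] / sqrt(se2[ok])
  p[ok] <- 2 * pt(-abs(tstat), df)
  p[degen] <- ifelse(log2fc[degen] == 0, 1, .Machine$double.xmin)
  q <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(mat), log2fc = log2fc, p = p, q = q,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select significantly induced genes from a contrast
#'
#' A gene is induced when `log2fc > fc_threshold` **and**
#' `q < q_threshold`, both inequalities strict.
#'
#' @param results Contrast `data.frame` from [contrast()].
#' @param fc_threshold log2 fold-change threshold (default 1, i.e.
#'   2-fold).
#' @param q_threshold BH-adjusted p-value threshold (default 0.05).
#' @return Character vector of selected gene ids (sorted).
#' @export
select_induced <- function(results, fc_threshold = 1,
                           q_threshold = 0.05) {
  stopifnot(fc_threshold > 0, q_threshold > 0)
  if (is.null(results) || nrow(results) == 0L) return(character())
  sort(results$gene[results$log2fc > fc_threshold &
                      results$q < q_threshold])
}

#' Select genes cooperatively induced by the drug combination
#'
#' A gene is *cooperatively induced* when it passes [select_induced()] in
#' all three contrasts: Combo-vs-DMSO, Combo-vs-HDACi and Combo-vs-EZH2i.
#' Genes induced equally by a single agent and the combination fail the
#' corresponding Combo-vs-single-agent contrast and drop out.
#'
#' @inheritParams contrast
#' @inheritParams select_induced
#' @param combo,dmso,ezh2i,hdaci Condition labels used for the four arms.
#' @return Character vector of cooperatively induced gene ids (sorted).
#' @export
select_cooperative <- function(se, fc_threshold = 1, q_threshold = 0.05,
                               combo = "Combo", dmso = "DMSO",
                               ezh2i = "EZH2i", hdaci = "HDACi") {
  for (cond in c(combo, dmso, ezh2i, hdaci)) condition_columns(se, cond)
  sel <- lapply(c(dmso, hdaci, ezh2i), function(ref)
    select_induced(contrast(se, combo, ref), fc_threshold, q_threshold))
  sort(Reduce(intersect, sel))
}
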