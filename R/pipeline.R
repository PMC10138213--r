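## End-to-end discovery orchestration: cooperative induction ->
## peak-loss calling -> candidate intersection, with provenance.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' In-memory candidate discovery
#'
#' Runs the three discovery stages on already-loaded objects: selects
#' cooperatively induced genes from the expression data, calls H3K27me3
#' peak loss (treated vs control) within promoter windows, and intersects
#' the two gene sets.
#'
#' @param se Expression `SummarizedExperiment` (assay `"log2"`,
#'   `condition` column data with all four arms).
#' @param control_peaks,treated_peaks Peak `data.frame`s (control =
#'   DMSO-like, treated = EZH2i-like).
#' @param ann Transcript annotation `data.frame`.
#' @param fc_threshold,q_threshold Induction thresholds (defaults 1 and
#'   0.05).
#' @param halfwidth Promoter window halfwidth in bp (default 10000).
#' @param protein_coding_only Restrict windows to protein-coding
#'   transcripts (default TRUE).
#' @param exclusions Optional exclusion list (see
#'   [intersect_candidates()]).
#' @param provenance Optional named list recorded in the report.
#' @return A `candidate_report` (see [intersect_candidates()]) whose
#'   provenance also records the thresholds used.
#' @export
discover_candidates <- function(se, control_peaks, treated_peaks, ann,
                                fc_threshold = 1, q_threshold = 0.05,
                                halfwidth = 10000,
                                protein_coding_only = TRUE,
                                exclusions = NULL,
                                provenance = list()) {
  cooperative <- stage("diffexpr",
    select_cooperative(se, fc_threshold, q_threshold))
  windows <- stage("peakloss",
    build_windows(ann, halfwidth, protein_coding_only))
  report <- stage("peakloss",
    call_lost(control_peaks, treated_peaks, windows))
  prc2 <- prc2_target_genes(report)
  provenance <- c(provenance,
                  list(fc_threshold = fc_threshold,
                       q_threshold = q_threshold,
                       halfwidth = halfwidth,
                       protein_coding_only = protein_coding_only))
  stage("integrate",
    intersect_candidates(cooperative, prc2, exclusions, provenance))
}

#' File-based end-to-end discovery run
#'
#' Reads every input from disk, executes [discover_candidates()], and
#' writes the candidate report, the per-contrast tables, the PRC2 target
#' gene list and a provenance block (MD5 digests of all inputs plus all
#' thresholds) under `outdir`.  Two runs on identical inputs produce
#' identical outputs.
#'
#' @param expression,sample_map Paths to the expression matrix TSV and
#'   sample map TSV (see [read_expression()]).
#' @param control_bed,treated_bed Paths to the control (DMSO) and treated
#'   (EZH2i) peak BED files.
#' @param annotation Path to the annotation TSV.
#' @param outdir Output directory (created if absent).
#' @inheritParams discover_candidates
#' @return Invisibly, the `candidate_report`.
#' @export
run_discovery <- function(expression, sample_map, control_bed,
                          treated_bed, annotation, outdir,
                          fc_threshold = 1, q_threshold = 0.05,
                          halfwidth = 10000,
                          protein_coding_only = TRUE,
                          exclusions = NULL) {
  inputs <- c(expression = expression, sample_map = sample_map,
              control_bed = control_bed, treated_bed = treated_bed,
              annotation = annotation)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0)
    stop("[input] missing file for '", names(missing)[1], "': ",
         missing[1], call. = FALSE)

  se <- stage("io", read_expression(expression, sample_map))
  control <- stage("io", read_bed(control_bed))
  treated <- stage("io", read_bed(treated_bed))
  ann <- stage("io", read_annotation(annotation))

  provenance <- list(inputs = as.list(
    setNames(unname(tools::md5sum(inputs)), names(inputs))))
  report <- discover_candidates(se, control, treated, ann,
                                fc_threshold, q_threshold, halfwidth,
                                protein_coding_only, exclusions,
                                provenance)

  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  for (ref in c("DMSO", "HDACi", "EZH2i")) {
    ct <- contrast(se, "Combo", ref)
    write.table(ct, file.path(outdir,
                              paste0("contrast_Combo_vs_", ref, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(report$prc2_targets,
             file.path(outdir, "prc2_target_genes.txt"))
  write_report(report, outdir)
  invisible(report)
}

#' Score planted-truth recovery of a candidate report
#'
#' Compares the candidate set against the planted cooperative class.
#'
#' @param report A `candidate_report`.
#' @param truth A `planted_truth` from [plant_truth()] (or a character
#'   vector of true gene ids).
#' @return A list: `sensitivity`, `precision`, `n_true`, `n_called`,
#'   `true_positives`.
#' @export
recovery_stats <- function(report, truth) {
  true_set <- if (inherits(truth, "planted_truth"))
    names(truth$gene_class)[truth$gene_class == "cooperative_prc2"]
  else as.character(truth)
  called <- report$candidates
  tp <- length(intersect(called, true_set))
  list(sensitivity = if (length(true_set) > 0) tp / length(true_set)
       else NA_real_,
       precision = if (length(called) > 0) tp / length(called)
       else NA_real_,
       n_true = length(true_set), n_called = length(called),
       true_positives = tp)
}
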