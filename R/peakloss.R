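## Differential peak-loss analysis: promoter window construction,
## peak-to-transcript assignment, lost-peak calling and gene-level
## aggregation.  Coordinates are 0-based half-open throughout; overlap
## means >= 1 bp shared, so touching intervals do not overlap.

#' Build promoter windows around transcript start sites
#'
#' One symmetric, strand-blind window `[TSS - W, TSS + W)` per retained
#' transcript, clipped at coordinate 0.  Transcripts whose biotype is not
#' `protein_coding` are dropped when `protein_coding_only` is set.
#'
#' @param ann Transcript annotation `data.frame` (see
#'   [read_annotation()]).
#' @param halfwidth Window halfwidth W in bp (default 10000, i.e. a 20-kb
#'   window).
#' @param protein_coding_only Drop non-coding transcripts (default TRUE).
#' @return A `data.frame` with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`.
#' @examples
#' ann <- data.frame(transcript_id = "T1", gene_id = "G1", chrom = "chr1",
#'                   strand = "+", tss = 50000, biotype = "protein_coding")
#' build_windows(ann)  # [40000, 60000)
#' @export
build_windows <- function(ann, halfwidth = 10000,
                          protein_coding_only = TRUE) {
  stopifnot(halfwidth > 0)
  if (protein_coding_only)
    ann <- ann[ann$biotype == "protein_coding", , drop = FALSE]
  if (nrow(ann) == 0L) {
    warning("no transcripts retained; returning empty window set")
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(transcript_id = ann$transcript_id, gene_id = ann$gene_id,
             chrom = ann$chrom,
             start = pmax(0, ann$tss - halfwidth),
             end = ann$tss + halfwidth,
             row.names = NULL, stringsAsFactors = FALSE)
}

## findOverlaps on 0-based half-open intervals; returns a hits data.frame
## (query = windows row, subject = peaks row).  Shifting both sets to
## 1-based closed coordinates preserves >= 1 bp overlap semantics.
overlap_hits <- function(windows, peaks) {
  if (nrow(windows) == 0L || nrow(peaks) == 0L)
    return(data.frame(window = integer(), peak = integer()))
  q <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$start + 1, end = windows$end))
  s <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  data.frame(window = S4Vectors::queryHits(hits),
             peak = S4Vectors::subjectHits(hits))
}

#' Assign peaks to promoter windows
#'
#' A peak is assigned to a transcript iff it overlaps the transcript's
#' window by at least 1 bp (half-open semantics); a peak may be assigned
#' to multiple transcripts and assignment is strand-blind.  Peaks on
#' chromosomes absent from the annotation are ignored (with a message).
#'
#' @param windows Window `data.frame` from [build_windows()].
#' @param peaks Peak `data.frame` (see [read_bed()]).
#' @return A `data.frame` with one row per (transcript, peak) assignment:
#'   `transcript_id`, `gene_id`, `peak_row` (row index into `peaks`),
#'   `peak_name`.
#' @export
assign_peaks <- function(windows, peaks) {
  validate_peaks(peaks)
  orphan <- setdiff(unique(peaks$chrom), unique(windows$chrom))
  if (length(orphan) > 0) {
    n_orphan <- sum(peaks$chrom %in% orphan)
    message(n_orphan, " peak(s) on ", length(orphan),
            " chromosome(s) absent from the annotation were ignored")
  }
  hits <- overlap_hits(windows, peaks)
  data.frame(
    transcript_id = windows$transcript_id[hits$window],
    gene_id = windows$gene_id[hits$window],
    peak_row = hits$peak,
    peak_name = if ("name" %in% names(peaks))
      peaks$name[hits$peak] else NA_character_,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Call lost peaks between a control and a treated condition
#'
#' Each control peak assigned to a promoter window is *retained* iff at
#' least one treated peak overlaps it by >= 1 bp, else *lost*.  A
#' transcript is flagged lost when >= 1 of its in-window control peaks is
#' lost; a gene is flagged lost when >= 1 of its transcripts is.
#'
#' @param control,treated Peak `data.frame`s for the control (e.g. DMSO)
#'   and treated (e.g. EZH2i) conditions.
#' @param windows Window `data.frame` from [build_windows()].
#' @return A list of class `peak_loss_report`: `transcripts` (per
#'   transcript: `transcript_id`, `gene_id`, `n_control_peaks`, `n_lost`,
#'   `lost`), `genes` (`gene_id`, `lost`), and `peak_status` (per assigned
#'   control peak: `transcript_id`, `peak_row`, `matched`).
#' @examples
#' ann <- data.frame(transcript_id = "T1", gene_id = "G1", chrom = "chr1",
#'                   strand = "+", tss = 50000, biotype = "protein_coding")
#' w <- build_windows(ann)
#' ctrl <- data.frame(chrom = "chr1", start = 45000, end = 46000)
#' call_lost(ctrl, ctrl[0, ], w)$genes
#' @export
call_lost <- function(control, treated, windows) {
  validate_peaks(control)
  validate_peaks(treated)
  assigned <- overlap_hits(windows, control)
  if (nrow(control) > 0 && nrow(treated) > 0) {
    ct_hits <- overlap_hits(control, treated)
    matched_peaks <- unique(ct_hits$window)   # control rows w/ a match
  } else {
    matched_peaks <- integer()
  }
  matched <- assigned$peak %in% matched_peaks

  peak_status <- data.frame(
    transcript_id = windows$transcript_id[assigned$window],
    peak_row = assigned$peak,
    matched = matched,
    row.names = NULL, stringsAsFactors = FALSE)

  n_ctrl <- tabulate(assigned$window, nbins = nrow(windows))
  n_lost <- tabulate(assigned$window[!matched], nbins = nrow(windows))
  transcripts <- data.frame(
    transcript_id = windows$transcript_id,
    gene_id = windows$gene_id,
    n_control_peaks = n_ctrl,
    n_lost = n_lost,
    lost = n_lost > 0,
    row.names = NULL, stringsAsFactors = FALSE)

  if (nrow(transcripts) > 0) {
    gene_lost <- tapply(transcripts$lost, transcripts$gene_id, any)
    genes <- data.frame(gene_id = names(gene_lost),
                        lost = as.logical(gene_lost),
                        row.names = NULL, stringsAsFactors = FALSE)
  } else {
    genes <- data.frame(gene_id = character(), lost = logical(),
                        stringsAsFactors = FALSE)
  }
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(transcripts = transcripts, genes = genes,
                 peak_status = peak_status),
            class = "peak_loss_report")
}

#' @export
print.peak_loss_report <- function(x, ...) {
  cat("Peak-loss report: ", sum(x$genes$lost), " of ", nrow(x$genes),
      " genes flagged lost (", sum(x$transcripts$lost), " of ",
      nrow(x$transcripts), " transcripts)\n", sep = "")
  invisible(x)
}

#' Extract PRC2 target genes from a peak-loss report
#'
#' PRC2 targets are genes whose promoter windows lost at least one
#' H3K27me3 peak in the treated condition (typically EZH2i vs DMSO).
#'
#' @param report A `peak_loss_report` from [call_lost()].
#' @param path Optional path; when given, the gene symbols are written one
#'   per line.
#' @return Character vector of lost-flagged gene ids (sorted).
#' @export
prc2_target_genes <- function(report, path = NULL) {
  stopifnot(inherits(report, "peak_loss_report"))
  genes <- sort(report$genes$gene_id[report$genes$lost])
  if (!is.null(path)) writeLines(genes, path)
  genes
}
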