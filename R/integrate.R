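## Candidate nomination: intersect cooperatively induced genes with PRC2
## target genes, record the Venn structure and full provenance.

#' Intersect cooperative genes with PRC2 targets
#'
#' Candidates are the exact set intersection of the cooperatively induced
#' genes and the PRC2 target (peak-loss) genes.  An optional exclusion
#' list removes symbols *after* the intersection, with the reason
#' recorded — this mirrors manual biological deprioritization (e.g. of
#' HLA genes) as declarative configuration rather than code.
#'
#' @param cooperative Character vector of cooperatively induced gene ids.
#' @param prc2_targets Character vector of PRC2 target gene ids.
#' @param exclusions Optional: either a character vector of symbols or a
#'   `data.frame` with columns `symbol` and `reason`.
#' @param provenance Optional named list recorded verbatim in the report
#'   (input digests, thresholds, seed, ...).
#' @return A list of class `candidate_report`: `cooperative`,
#'   `prc2_targets`, `intersection`, `candidates` (post-exclusion),
#'   `excluded` (`data.frame` of applied exclusions), `venn` (named
#'   counts `only_cooperative`, `only_prc2`, `both`), `provenance`.
#' @examples
#' r <- intersect_candidates(c("A", "B", "C"), c("B", "C", "D"))
#' r$venn
#' @export
intersect_candidates <- function(cooperative, prc2_targets,
                                 exclusions = NULL,
                                 provenance = list()) {
  cooperative <- sort(unique(as.character(cooperative)))
  prc2_targets <- sort(unique(as.character(prc2_targets)))
  both <- intersect(cooperative, prc2_targets)
  if (is.null(exclusions)) {
    excl <- data.frame(symbol = character(), reason = character(),
                       stringsAsFactors = FALSE)
  } else if (is.data.frame(exclusions)) {
    stopifnot(all(c("symbol", "reason") %in% names(exclusions)))
    excl <- exclusions[, c("symbol", "reason"), drop = FALSE]
  } else {
    excl <- data.frame(symbol = as.character(exclusions),
                       reason = "excluded by configuration",
                       stringsAsFactors = FALSE)
  }
  excl <- excl[excl$symbol %in% both, , drop = FALSE]
  rownames(excl) <- NULL
  candidates <- setdiff(both, excl$symbol)
  structure(list(
    cooperative = cooperative,
    prc2_targets = prc2_targets,
    intersection = both,
    candidates = candidates,
    excluded = excl,
    venn = c(only_cooperative = length(setdiff(cooperative, both)),
             only_prc2 = length(setdiff(prc2_targets, both)),
             both = length(both)),
    provenance = provenance
  ), class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Candidate report\n")
  cat("  cooperatively induced: ", length(x$cooperative),
      "  |  PRC2 targets: ", length(x$prc2_targets),
      "  |  overlap: ", x$venn[["both"]], "\n", sep = "")
  cat("  final candidates (", length(x$candidates), "): ",
      paste(head(x$candidates, 8), collapse = ", "),
      if (length(x$candidates) > 8) ", ..." else "", "\n", sep = "")
  if (nrow(x$excluded) > 0)
    cat("  excluded: ", paste(x$excluded$symbol, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Write a candidate report as TSV + JSON
#'
#' Outputs are deterministic: identical inputs yield byte-identical files.
#'
#' @param report A `candidate_report` from [intersect_candidates()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "candidate_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "candidates.tsv")
  all_genes <- sort(unique(c(report$cooperative, report$prc2_targets)))
  df <- data.frame(
    gene = all_genes,
    cooperative = all_genes %in% report$cooperative,
    prc2_target = all_genes %in% report$prc2_targets,
    candidate = all_genes %in% report$candidates,
    stringsAsFactors = FALSE)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(dir, "candidates.json")
  jsonlite::write_json(list(
    venn = as.list(report$venn),
    candidates = report$candidates,
    excluded = report$excluded,
    provenance = report$provenance
  ), js, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = js))
}
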