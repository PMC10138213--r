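## Readers/writers for the external formats the pipeline touches.
## All genomic coordinates are 0-based half-open (BED convention)
## end-to-end; any 1-based source must be converted at this boundary.

#' Read a BED file of genomic intervals
#'
#' Accepts BED3+ (tab-separated, no header).  Columns beyond the sixth are
#' ignored; `track`/`browser`/comment lines are skipped.  Output is sorted
#' canonically by `(chrom, start, end)` so reader output is independent of
#' input line order.
#'
#' @param path Path to a BED file.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (0-based half-open coordinates).
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tpk1\t60\t+", f)
#' read_bed(f)
#' @export
read_bed <- function(path) {
  if (!file.exists(path))
    stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) &
    nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(empty_peaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L)) {
    bad <- lineno[which(ncols < 3L)[1]]
    stop("BED parse error at line ", bad, ": fewer than 3 columns",
         call. = FALSE)
  }
  get <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  chrom <- get(1)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad) > 0)
    stop("BED parse error at line ", lineno[bad[1]],
         ": non-integer coordinates", call. = FALSE)
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0)
    stop("BED parse error at line ", lineno[bad[1]],
         ": requires 0 <= start < end", call. = FALSE)
  name <- get(4)
  score <- suppressWarnings(as.numeric(get(5)))
  strand <- get(6)
  strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "."
  df <- data.frame(chrom = chrom, start = start, end = end,
                   name = ifelse(is.na(name), ".", name),
                   score = ifelse(is.na(score), 0, score),
                   strand = strand, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' @param peaks Interval `data.frame` as returned by [read_bed()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(peaks, path) {
  validate_peaks(peaks)
  df <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$chrom, as.integer(df$start),
                 as.integer(df$end), df$name,
                 format(df$score, trim = TRUE, scientific = FALSE),
                 df$strand)
  writeLines(out, path)
  invisible(path)
}

validate_peaks <- function(peaks) {
  req <- c("chrom", "start", "end")
  if (!is.data.frame(peaks) || !all(req %in% names(peaks)))
    stop("peaks must be a data.frame with chrom/start/end columns",
         call. = FALSE)
  if (nrow(peaks) > 0) {
    if (any(!nzchar(peaks$chrom)))
      stop("empty chromosome name in peak set", call. = FALSE)
    if (any(peaks$start >= peaks$end | peaks$start < 0))
      stop("invalid interval: requires 0 <= start < end", call. = FALSE)
  }
  invisible(peaks)
}

#' Construct a gene set
#'
#' Members are deduplicated case-sensitively, preserving first occurrence.
#'
#' @param name Nonempty set name.
#' @param description Free-text description.
#' @param members Character vector of gene symbols (>= 1 after dedup).
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(name, description = "", members) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene set name must be a nonempty string", call. = FALSE)
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  if (length(members) == 0L)
    stop("gene set '", name, "' has no members", call. = FALSE)
  structure(list(name = name, description = description,
                 members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$name, "' (", length(x$members), " members): ",
      paste(head(x$members, 5), collapse = ", "),
      if (length(x$members) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Broad-dialect GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`.  Duplicate members
#' within a set are collapsed; duplicate set names are an error.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of [gene_set()] objects (empty list for an empty
#'   file).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(structure(list(), names = character()))
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i,
           ": expected name, description and >= 1 member", call. = FALSE)
    sets[[i]] <- gene_set(f[1], f[2], f[-(1:2)])
    nms[i] <- f[1]
  }
  dup <- nms[duplicated(nms)]
  if (length(dup) > 0)
    stop("duplicate gene set name in GMT: ", dup[1], call. = FALSE)
  names(sets) <- nms
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a normalized log2 expression matrix with its sample map
#'
#' The matrix TSV has a header row of sample ids and first column of gene
#' ids; the sample map TSV has columns `sample` and `condition` (and
#' optionally `replicate`).  Every matrix column must appear in the map,
#' gene ids must be unique, and all cells must be finite numbers.
#'
#' @param matrix_path Path to the expression TSV.
#' @param sample_map_path Path to the sample map TSV.
#' @param conditions Declared set of admissible condition labels.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"log2"` and column data `sample`, `condition`.
#' @export
read_expression <- function(matrix_path, sample_map_path,
                            conditions = c("DMSO", "EZH2i", "HDACi",
                                           "Combo")) {
  raw <- read.delim(matrix_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  gene <- as.character(raw[[1]])
  if (anyDuplicated(gene))
    stop("duplicated gene id in expression matrix: ",
         gene[duplicated(gene)][1], call. = FALSE)
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat) || any(!is.finite(mat))) {
    bad <- which(!is.finite(suppressWarnings(
      matrix(as.numeric(mat), nrow(mat)))))[1]
    stop("non-numeric or non-finite expression value (cell index ", bad,
         ")", call. = FALSE)
  }
  rownames(mat) <- gene
  smap <- read.delim(sample_map_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(smap)))
    stop("sample map needs 'sample' and 'condition' columns",
         call. = FALSE)
  missing <- setdiff(colnames(mat), smap$sample)
  if (length(missing) > 0)
    stop("sample '", missing[1], "' present in matrix but not in ",
         "sample map", call. = FALSE)
  smap <- smap[match(colnames(mat), smap$sample), , drop = FALSE]
  badc <- setdiff(unique(smap$condition), conditions)
  if (length(badc) > 0)
    stop("unknown condition '", badc[1], "' in sample map", call. = FALSE)
  coldata <- S4Vectors::DataFrame(sample = smap$sample,
                                  condition = smap$condition,
                                  row.names = smap$sample)
  if ("replicate" %in% names(smap)) coldata$replicate <- smap$replicate
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = mat), colData = coldata)
}

#' Write an expression SummarizedExperiment as matrix + sample map TSVs
#'
#' @param se A `SummarizedExperiment` with assay `"log2"` and a
#'   `condition` column in its column data.
#' @param matrix_path,sample_map_path Output paths.
#' @return Invisibly, `matrix_path`.
#' @export
write_expression <- function(se, matrix_path, sample_map_path) {
  mat <- SummarizedExperiment::assay(se, "log2")
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  write.table(cd, sample_map_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(matrix_path)
}

#' Read / write the transcript annotation TSV
#'
#' Columns: `transcript_id`, `gene_id`, `gene_name`, `chrom`, `strand`,
#' `tss`, `biotype`.
#'
#' @param path Path to the annotation TSV.
#' @return `read_annotation`: the annotation `data.frame`.
#' @export
read_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("transcript_id", "gene_id", "chrom", "strand", "tss",
           "biotype")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0)
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ann$transcript_id))
    stop("duplicated transcript_id in annotation", call. = FALSE)
  if (any(ann$tss < 0)) stop("negative TSS in annotation", call. = FALSE)
  ann
}

#' @rdname read_annotation
#' @param ann Annotation `data.frame`.
#' @export
write_annotation <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a tumor-cohort table
#'
#' Columns: `sample`, `class` (one of `normal`, `primary`, `metastatic`),
#' optional `time` / `event`, then one column per gene.
#'
#' @param path Path to the cohort TSV.
#' @return `read_cohort`: the cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "class") %in% names(df)))
    stop("cohort table needs 'sample' and 'class' columns", call. = FALSE)
  badc <- setdiff(unique(df$class), c("normal", "primary", "metastatic"))
  if (length(badc) > 0)
    stop("unknown tissue class '", badc[1], "'", call. = FALSE)
  if ("time" %in% names(df)) {
    if (any(df$time < 0, na.rm = TRUE))
      stop("negative survival time", call. = FALSE)
    if (!"event" %in% names(df) ||
        any(is.na(df$event[!is.na(df$time)])))
      stop("event indicator must be defined wherever time is",
           call. = FALSE)
  }
  df
}

#' @rdname read_cohort
#' @param cohort Cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a dose-response matrix CSV
#'
#' Layout: first row = doses of drug B, first column = doses of drug A,
#' body = % inhibition.
#'
#' @param path Path to the CSV.
#' @return `read_dose_matrix`: a [dose_response()] object.
#' @export
read_dose_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  doses_a <- as.numeric(raw[[1]])
  doses_b <- as.numeric(names(raw)[-1])
  resp <- as.matrix(raw[, -1, drop = FALSE])
  dimnames(resp) <- list(doses_a, doses_b)
  dose_response(doses_a, doses_b, resp)
}

#' @rdname read_dose_matrix
#' @param dose A [dose_response()] object.
#' @export
write_dose_matrix <- function(dose, path) {
  df <- data.frame(dose_a = dose$doses_a, dose$response,
                   check.names = FALSE)
  names(df) <- c("dose_a", dose$doses_b)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
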