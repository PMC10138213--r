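## Synthetic study generator: every input the discovery pipeline consumes,
## with planted ground truth, so downstream stages are testable offline.

#' Configuration for the synthetic study generator
#'
#' Bundles every parameter of the synthetic data generator into a validated
#' configuration object.  The defaults describe the emulated study design:
#' a four-condition (DMSO, EZH2i, HDACi, Combo) microarray-like experiment
#' with 3 replicates per arm, planted gene classes, per-condition H3K27me3
#' peak landscapes with losses planted at cooperative-target promoters, a
#' three-class tumor cohort (normal / primary / metastatic) with an
#' EZH2-high, ATF3-low gradient and ATF3-dependent survival, and a
#' dose-response surface with a known excess over the highest-single-agent
#' reference.
#'
#' @param seed Integer master seed.  Split internally into independent
#'   named substreams (annotation, truth, peaks, expression, cohort, dose)
#'   so regenerating one input does not perturb the others.
#' @param n_genes Number of genes in the annotation/expression universe.
#' @param n_planted_cooperative Genes induced only by the combination and
#'   carrying a planted promoter H3K27me3 loss under EZH2i/Combo.
#' @param n_planted_ezh2i_only,n_planted_hdaci_only Genes induced by one
#'   single agent (and hence also by the combination); they fail the
#'   "unique to combo" contrasts by construction.
#' @param n_planted_additive Genes induced by the combination only, but
#'   without planted peak loss; the candidate intersection removes them.
#' @param n_replicates_per_condition Replicates per arm (must be >= 2).
#' @param effect_log2fc Planted induction magnitude on the log2 scale.
#' @param noise_sd Residual Gaussian SD on the log2 scale.  May be 0 for
#'   noiseless fixtures in which planted effects are recovered exactly.
#' @param genome_n_chroms,chrom_length Synthetic genome shape (bp).
#' @param tss_window_halfwidth Promoter window halfwidth W in bp; windows
#'   span `[TSS - W, TSS + W)`.
#' @param cohort_n_normal,cohort_n_primary,cohort_n_metastatic Cohort
#'   tissue-class sizes.
#' @param ezh2_shift_primary,ezh2_shift_metastatic Planted EZH2 expression
#'   mean shifts (in units of the normal-class SD) for primary and
#'   metastatic samples.
#' @param atf3_shift_primary,atf3_shift_metastatic Planted ATF3 shifts
#'   (negative: ATF3 decreases with progression).
#' @param signature_coupling Latent correlation between per-sample PRC2
#'   derepression activity and ATF3 activity in the cohort.
#' @param signature_gene_sd Per-gene residual SD around the latent activity
#'   for signature genes.
#' @param hazard_ratio_atf3_low Relative hazard of ATF3-low (below-median
#'   latent ATF3 activity) samples; must be > 0.
#' @param censor_rate Fraction of samples independently censored, in
#'   `[0, 1)`.
#' @param dose_grid_a,dose_grid_b Increasing dose grids including 0
#'   (defaults: the EZH2i and HDACi dose series used in the emulated
#'   viability assay, in uM).
#' @param planted_hsa_excess Constant excess (percentage points) of every
#'   both-positive-dose combination well over its HSA reference.
#'
#' @return An object of class `synth_config` (a validated named list).
#' @examples
#' cfg <- synth_config(seed = 1, n_genes = 100)
#' cfg$n_genes
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 1000L,
                         n_planted_cooperative = 30L,
                         n_planted_ezh2i_only = 20L,
                         n_planted_hdaci_only = 20L,
                         n_planted_additive = 20L,
                         n_replicates_per_condition = 3L,
                         effect_log2fc = 2,
                         noise_sd = 0.25,
                         genome_n_chroms = 4L,
                         chrom_length = 1.2e7,
                         tss_window_halfwidth = 10000L,
                         cohort_n_normal = 28L,
                         cohort_n_primary = 59L,
                         cohort_n_metastatic = 35L,
                         ezh2_shift_primary = 2,
                         ezh2_shift_metastatic = 4.4,
                         atf3_shift_primary = -1,
                         atf3_shift_metastatic = -2,
                         signature_coupling = 0.7,
                         signature_gene_sd = 0.4,
                         hazard_ratio_atf3_low = 3,
                         censor_rate = 0.3,
                         dose_grid_a = c(0, 1.25, 2.5, 5, 10),
                         dose_grid_b = c(0, 0.5, 1, 2, 4, 8),
                         planted_hsa_excess = 15) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_planted_cooperative = as.integer(n_planted_cooperative),
    n_planted_ezh2i_only = as.integer(n_planted_ezh2i_only),
    n_planted_hdaci_only = as.integer(n_planted_hdaci_only),
    n_planted_additive = as.integer(n_planted_additive),
    n_replicates_per_condition = as.integer(n_replicates_per_condition),
    effect_log2fc = effect_log2fc,
    noise_sd = noise_sd,
    genome_n_chroms = as.integer(genome_n_chroms),
    chrom_length = as.numeric(chrom_length),
    tss_window_halfwidth = as.integer(tss_window_halfwidth),
    cohort_n_normal = as.integer(cohort_n_normal),
    cohort_n_primary = as.integer(cohort_n_primary),
    cohort_n_metastatic = as.integer(cohort_n_metastatic),
    ezh2_shift_primary = ezh2_shift_primary,
    ezh2_shift_metastatic = ezh2_shift_metastatic,
    atf3_shift_primary = atf3_shift_primary,
    atf3_shift_metastatic = atf3_shift_metastatic,
    signature_coupling = signature_coupling,
    signature_gene_sd = signature_gene_sd,
    hazard_ratio_atf3_low = hazard_ratio_atf3_low,
    censor_rate = censor_rate,
    dose_grid_a = as.numeric(dose_grid_a),
    dose_grid_b = as.numeric(dose_grid_b),
    planted_hsa_excess = planted_hsa_excess
  )
  counts <- c("n_genes", "n_planted_cooperative", "n_planted_ezh2i_only",
              "n_planted_hdaci_only", "n_planted_additive",
              "n_replicates_per_condition", "genome_n_chroms",
              "cohort_n_normal", "cohort_n_primary", "cohort_n_metastatic")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L)
      stop("'", nm, "' must be a nonnegative count", call. = FALSE)
  }
  if (cfg$n_genes < 1L)
    stop("'n_genes' must be >= 1", call. = FALSE)
  planted <- cfg$n_planted_cooperative + cfg$n_planted_ezh2i_only +
    cfg$n_planted_hdaci_only + cfg$n_planted_additive
  if (planted > cfg$n_genes)
    stop("planted gene counts (", planted, ") exceed n_genes (",
         cfg$n_genes, ")", call. = FALSE)
  if (cfg$noise_sd < 0)
    stop("'noise_sd' must be >= 0", call. = FALSE)
  if (cfg$tss_window_halfwidth <= 0L)
    stop("'tss_window_halfwidth' must be > 0", call. = FALSE)
  if (cfg$hazard_ratio_atf3_low <= 0)
    stop("'hazard_ratio_atf3_low' must be > 0", call. = FALSE)
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("'censor_rate' must lie in [0, 1)", call. = FALSE)
  if (abs(cfg$signature_coupling) > 1)
    stop("'signature_coupling' must lie in [-1, 1]", call. = FALSE)
  for (grid in c("dose_grid_a", "dose_grid_b")) {
    g <- cfg[[grid]]
    if (length(g) < 2L || g[1] != 0 || any(diff(g) <= 0))
      stop("'", grid, "' must start at 0 and strictly increase",
           call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic study configuration (seed ", x$seed, ")\n", sep = "")
  cat("  genes: ", x$n_genes, " (cooperative ", x$n_planted_cooperative,
      ", additive ", x$n_planted_additive, ", EZH2i-only ",
      x$n_planted_ezh2i_only, ", HDACi-only ", x$n_planted_hdaci_only,
      ")\n", sep = "")
  cat("  expression: 4 conditions x ", x$n_replicates_per_condition,
      " replicates, effect ", x$effect_log2fc, " log2, noise SD ",
      x$noise_sd, "\n", sep = "")
  cat("  cohort: ", x$cohort_n_normal, " normal / ", x$cohort_n_primary,
      " primary / ", x$cohort_n_metastatic, " metastatic\n", sep = "")
  invisible(x)
}

## Deterministic per-purpose substream seeds derived from the master seed.
substream_seeds <- function(config) {
  set.seed(config$seed)
  s <- sample.int(.Machine$integer.max - 1L, 6L)
  names(s) <- c("annotation", "truth", "peaks", "expression",
                "cohort", "dose")
  s
}

#' Generate a synthetic transcript annotation
#'
#' Places gene TSS on a synthetic genome with inter-TSS spacing of at least
#' three window halfwidths, so no promoter window can capture a neighboring
#' gene's peaks.  Each gene carries one or two transcripts (alternative TSS
#' within 500 bp); at least 90% of genes are protein-coding, the remainder
#' noncoding to exercise the biotype filter.
#'
#' @param config A [synth_config()] object.
#' @return A `data.frame` with columns `transcript_id`, `gene_id`,
#'   `gene_name`, `chrom`, `strand`, `tss`, `biotype`.
#' @examples
#' ann <- generate_annotation(synth_config(seed = 1, n_genes = 20))
#' head(ann)
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  W <- config$tss_window_halfwidth
  L <- config$chrom_length
  spacing <- 4 * W              # slot pitch; jitter < W keeps gaps >= 3W
  ## slot k (0-based) occupies TSS in [W + k*spacing, W + k*spacing + W);
  ## the window must end before L, so the last admissible slot satisfies
  ## W + k*spacing + W + W <= L.
  slots_per_chrom <- floor((L - 3 * W) / spacing) + 1
  if (slots_per_chrom < 1) slots_per_chrom <- 0
  capacity <- slots_per_chrom * config$genome_n_chroms
  if (capacity < config$n_genes) {
    per_chrom <- ceiling(config$n_genes / config$genome_n_chroms)
    min_len <- 3 * W + (per_chrom - 1) * spacing
    stop("genome too small: ", config$n_genes, " genes need chromosomes ",
         "of at least ", min_len, " bp at halfwidth ", W,
         " (chrom_length is ", format(L, scientific = FALSE), ")",
         call. = FALSE)
  }
  set.seed(substream_seeds(config)[["annotation"]])
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  chrom_idx <- rep(seq_len(config$genome_n_chroms),
                   length.out = config$n_genes)
  slot <- integer(config$n_genes)
  for (ch in unique(chrom_idx)) {
    sel <- which(chrom_idx == ch)
    slot[sel] <- seq_along(sel) - 1L
  }
  jitter <- floor(runif(config$n_genes, 0, W))
  tss <- W + slot * spacing + jitter
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  n_noncoding <- floor(0.05 * config$n_genes)
  biotype <- rep("protein_coding", config$n_genes)
  if (n_noncoding > 0) {
    ## noncoding genes are drawn from the tail of the id list so planted
    ## classes (assigned among coding genes by plant_truth) never collide
    biotype[sample(seq_len(config$n_genes), n_noncoding)] <- "noncoding"
  }
  two_tx <- runif(config$n_genes) < 0.3
  rows <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    n_tx <- if (two_tx[i]) 2L else 1L
    offs <- if (n_tx == 2L) c(0L, sample(100:500, 1L)) else 0L
    rows[[i]] <- data.frame(
      transcript_id = sprintf("%s.T%d", gene_ids[i], seq_len(n_tx)),
      gene_id = gene_ids[i],
      gene_name = gene_ids[i],
      chrom = sprintf("chr%d", chrom_idx[i]),
      strand = strand[i],
      tss = tss[i] + offs,
      biotype = biotype[i],
      stringsAsFactors = FALSE
    )
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  ann
}

#' Plant ground-truth gene classes and promoter peak losses
#'
#' Assigns every gene exactly one class from `cooperative_prc2`,
#' `ezh2i_only`, `hdaci_only`, `additive`, or `null`; planted classes are
#' drawn among protein-coding genes only.  Every cooperative gene receives
#' one transcript with a planted H3K27me3 loss under EZH2i and Combo.
#'
#' @param config A [synth_config()] object.
#' @param ann Annotation from [generate_annotation()].
#' @return A list of class `planted_truth`: `gene_class` (named character
#'   vector over all genes) and `loss_transcripts` (transcript ids with
#'   planted loss).
#' @export
plant_truth <- function(config, ann) {
  stopifnot(inherits(config, "synth_config"), is.data.frame(ann))
  set.seed(substream_seeds(config)[["truth"]])
  genes <- unique(ann$gene_id)
  coding <- unique(ann$gene_id[ann$biotype == "protein_coding"])
  n_need <- config$n_planted_cooperative + config$n_planted_ezh2i_only +
    config$n_planted_hdaci_only + config$n_planted_additive
  if (length(coding) < n_need)
    stop("not enough protein-coding genes (", length(coding),
         ") for ", n_need, " planted genes", call. = FALSE)
  picked <- sample(coding, n_need)
  cls <- setNames(rep("null", length(genes)), genes)
  idx <- 0L
  for (spec in list(c("cooperative_prc2", config$n_planted_cooperative),
                    c("ezh2i_only", config$n_planted_ezh2i_only),
                    c("hdaci_only", config$n_planted_hdaci_only),
                    c("additive", config$n_planted_additive))) {
    k <- as.integer(spec[2])
    if (k > 0) cls[picked[idx + seq_len(k)]] <- spec[1]
    idx <- idx + k
  }
  coop <- names(cls)[cls == "cooperative_prc2"]
  loss_tx <- vapply(coop, function(g) {
    tx <- ann$transcript_id[ann$gene_id == g &
                              ann$biotype == "protein_coding"]
    tx[1]
  }, character(1), USE.NAMES = FALSE)
  structure(list(gene_class = cls, loss_transcripts = loss_tx),
            class = "planted_truth")
}

#' Generate per-condition H3K27me3 peak landscapes
#'
#' The DMSO peak set contains a peak inside the promoter window of every
#' planted cooperative gene; EZH2i and Combo omit exactly those peaks
#' (planted loss); HDACi matches DMSO at planted targets.  Stable promoter
#' peaks at a subset of non-cooperative genes and intergenic background
#' peaks (outside every promoter window) are present in all conditions.
#'
#' @param config A [synth_config()] object.
#' @param ann Annotation from [generate_annotation()].
#' @param truth Planted truth from [plant_truth()].
#' @return Named list of peak `data.frame`s (columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`), one per condition, each sorted by
#'   `(chrom, start, end)`.
#' @export
generate_peaksets <- function(config, ann, truth) {
  stopifnot(inherits(config, "synth_config"),
            inherits(truth, "planted_truth"))
  set.seed(substream_seeds(config)[["peaks"]])
  W <- config$tss_window_halfwidth

  peak_at <- function(tx_rows, label, width = 2000L) {
    center <- tx_rows$tss
    data.frame(chrom = tx_rows$chrom,
               start = pmax(0, center - width %/% 2L),
               end = center + width %/% 2L,
               name = paste0(label, "_", tx_rows$transcript_id),
               score = 100,
               strand = ".",
               stringsAsFactors = FALSE)
  }

  loss_rows <- ann[match(truth$loss_transcripts, ann$transcript_id), ,
                   drop = FALSE]
  planted <- if (nrow(loss_rows) > 0) peak_at(loss_rows, "k27me3") else NULL

  ## stable promoter peaks: a random 20% of non-cooperative transcripts
  coop_genes <- names(truth$gene_class)[truth$gene_class ==
                                          "cooperative_prc2"]
  other_tx <- ann[!(ann$gene_id %in% coop_genes), , drop = FALSE]
  n_stable <- floor(0.2 * nrow(other_tx))
  stable <- if (n_stable > 0) {
    peak_at(other_tx[sample(nrow(other_tx), n_stable), , drop = FALSE],
            "stable")
  } else NULL

  ## intergenic background: offset 1.4 W downstream of a subset of TSS,
  ## guaranteed outside all windows because inter-TSS gaps exceed 3 W
  n_bg <- min(200L, nrow(ann))
  bg_rows <- ann[sample(nrow(ann), n_bg), , drop = FALSE]
  background <- data.frame(chrom = bg_rows$chrom,
                           start = bg_rows$tss + round(1.4 * W),
                           end = bg_rows$tss + round(1.4 * W) + 1000L,
                           name = paste0("bg_", bg_rows$transcript_id),
                           score = 50,
                           strand = ".",
                           stringsAsFactors = FALSE)

  common <- rbind(stable, background)
  sets <- list(
    DMSO = rbind(planted, common),
    EZH2i = common,
    HDACi = rbind(planted, common),
    Combo = common
  )
  lapply(sets, function(df) {
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

#' Generate a four-condition log2 expression matrix with planted effects
#'
#' Planted means on the log2 scale: cooperative and additive genes are
#' elevated by `effect_log2fc` in Combo only; `ezh2i_only` / `hdaci_only`
#' genes are elevated in their single-agent condition *and* in Combo (so
#' they fail the unique-to-combo contrasts); cooperative genes are not
#' elevated in either single agent.  Gaussian noise with SD `noise_sd` is
#' added on the log2 scale.
#'
#' @param config A [synth_config()] object
#'   (`n_replicates_per_condition >= 2`).
#' @param truth Planted truth from [plant_truth()].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"log2"` and column data `sample`, `condition`, `replicate`.
#' @export
generate_expression <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"),
            inherits(truth, "planted_truth"))
  if (config$n_replicates_per_condition < 2L)
    stop("need >= 2 replicates per condition for contrast tests",
         call. = FALSE)
  set.seed(substream_seeds(config)[["expression"]])
  conditions <- c("DMSO", "EZH2i", "HDACi", "Combo")
  reps <- config$n_replicates_per_condition
  genes <- names(truth$gene_class)
  n <- length(genes)

  baseline <- runif(n, 4, 10)
  eff <- config$effect_log2fc
  shift <- matrix(0, n, 4, dimnames = list(genes, conditions))
  cls <- truth$gene_class
  shift[cls == "cooperative_prc2", "Combo"] <- eff
  shift[cls == "additive", "Combo"] <- eff
  shift[cls == "ezh2i_only", c("EZH2i", "Combo")] <- eff
  shift[cls == "hdaci_only", c("HDACi", "Combo")] <- eff

  cols <- expand.grid(replicate = seq_len(reps), condition = conditions,
                      stringsAsFactors = FALSE)
  sample_id <- paste0(cols$condition, "_", cols$replicate)
  mat <- matrix(0, n, nrow(cols), dimnames = list(genes, sample_id))
  for (j in seq_len(nrow(cols))) {
    mu <- baseline + shift[, cols$condition[j]]
    noise <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else 0
    mat[, j] <- mu + noise
  }
  coldata <- S4Vectors::DataFrame(sample = sample_id,
                                  condition = cols$condition,
                                  replicate = cols$replicate,
                                  row.names = sample_id)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = mat), colData = coldata)
}

#' Gene sets used by the synthetic cohort
#'
#' Deterministic member lists for the two planted transcriptional
#' signatures: a PRC2-derepression signature (analogue of an EZH2-target
#' set) and an ATF3-activity signature.  Independent of the random seed.
#'
#' @param config A [synth_config()] object.
#' @return Named list of two [gene_set()] objects.
#' @export
cohort_gene_sets <- function(config) {
  list(
    PRC2_DEREPRESSION = gene_set(
      "PRC2_DEREPRESSION",
      "synthetic EZH2-target derepression signature",
      sprintf("ET%03d", 1:25)),
    ATF3_ACTIVITY = gene_set(
      "ATF3_ACTIVITY",
      "synthetic ATF3 stress-response signature",
      sprintf("AT%03d", 1:25))
  )
}

#' Generate a synthetic tumor cohort
#'
#' Per-sample tissue class (normal / primary / metastatic), marker-gene
#' expression with a planted EZH2-increasing / ATF3-decreasing gradient,
#' signature-gene expression driven by correlated latent PRC2-derepression
#' and ATF3 activities (coupling `signature_coupling`), background genes,
#' and exponential survival in which below-median latent-ATF3 samples have
#' their hazard multiplied by `hazard_ratio_atf3_low`, with independent
#' censoring at rate `censor_rate`.
#'
#' @param config A [synth_config()] object.
#' @return A `data.frame` with columns `sample`, `class`, `time`, `event`,
#'   marker genes `EZH2`, `ATF3`, signature genes `ET001..ET025` /
#'   `AT001..AT025`, and background genes `BG0001..BG0900` (per-gene
#'   baselines spread over a transcriptome-like dynamic range).  The
#'   latent per-sample activities are attached as `attr(, "latent")`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(substream_seeds(config)[["cohort"]])
  n_by_class <- c(normal = config$cohort_n_normal,
                  primary = config$cohort_n_primary,
                  metastatic = config$cohort_n_metastatic)
  n <- sum(n_by_class)
  if (n < 1L) stop("cohort is empty", call. = FALSE)
  cls <- rep(names(n_by_class), n_by_class)
  sample_id <- sprintf("S%03d", seq_len(n))

  ezh2_mu <- c(normal = 0, primary = config$ezh2_shift_primary,
               metastatic = config$ezh2_shift_metastatic)[cls]
  atf3_mu <- c(normal = 0, primary = config$atf3_shift_primary,
               metastatic = config$atf3_shift_metastatic)[cls]
  ezh2 <- ezh2_mu + rnorm(n)
  atf3 <- atf3_mu + rnorm(n)

  rho <- config$signature_coupling
  derepression <- rnorm(n)
  atf3_activity <- rho * derepression + sqrt(1 - rho^2) * rnorm(n)

  ## transcriptome-like expression: every gene has its own baseline
  ## log2 intensity spread over the array's dynamic range, so latent
  ## shifts move signature genes locally within the per-sample ranking
  ## (a small universe with all genes at one baseline would make the
  ## rank-based scores saturate and compress cohort correlations)
  sig_gene <- function(latent, ids) {
    base <- runif(length(ids), 4, 10)
    m <- vapply(seq_along(ids), function(i)
      base[i] + latent + rnorm(n, 0, config$signature_gene_sd),
      numeric(n))
    colnames(m) <- ids
    m
  }
  et <- sig_gene(derepression, sprintf("ET%03d", 1:25))
  at <- sig_gene(atf3_activity, sprintf("AT%03d", 1:25))
  n_bg <- 900L
  bg_base <- runif(n_bg, 4, 10)
  bg <- vapply(seq_len(n_bg), function(i) bg_base[i] + rnorm(n),
               numeric(n))
  colnames(bg) <- sprintf("BG%04d", seq_len(n_bg))

  ## exponential survival; ATF3-low = below-median latent ATF3 activity
  base_rate <- log(2) / 60          # median 60 time units for ATF3-high
  low <- atf3_activity < median(atf3_activity)
  rate <- base_rate * ifelse(low, config$hazard_ratio_atf3_low, 1)
  true_time <- rexp(n, rate)
  censored <- runif(n) < config$censor_rate
  time <- ifelse(censored, runif(n) * true_time, true_time)
  event <- as.integer(!censored)

  cohort <- data.frame(sample = sample_id, class = cls,
                       time = time, event = event,
                       EZH2 = ezh2, ATF3 = atf3,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, et, at, bg)
  rownames(cohort) <- NULL
  attr(cohort, "latent") <- data.frame(sample = sample_id,
                                       derepression = derepression,
                                       atf3_activity = atf3_activity,
                                       atf3_low = low)
  cohort
}

#' Generate a dose-response matrix with a planted HSA excess
#'
#' Single-agent responses follow monotone saturating (Emax) curves;
#' every both-positive-dose combination well equals its
#' highest-single-agent reference plus `planted_hsa_excess` percentage
#' points.  Responses are % inhibition relative to vehicle, so the (0, 0)
#' well is exactly 0.
#'
#' @param config A [synth_config()] object.
#' @return A [dose_response()] object.
#' @export
generate_dose_matrix <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  da <- config$dose_grid_a
  db <- config$dose_grid_b
  emax_a <- 40; ec50_a <- stats::median(da[da > 0])
  emax_b <- 60; ec50_b <- stats::median(db[db > 0])
  resp_a <- emax_a * da / (da + ec50_a)
  resp_b <- emax_b * db / (db + ec50_b)
  resp <- matrix(0, length(da), length(db),
                 dimnames = list(da, db))
  for (i in seq_along(da)) {
    for (j in seq_along(db)) {
      ref <- max(resp_a[i], resp_b[j])
      resp[i, j] <- if (da[i] > 0 && db[j] > 0)
        ref + config$planted_hsa_excess else ref
    }
  }
  dose_response(da, db, resp)
}

#' Write the complete synthetic bundle to disk
#'
#' Generates every pipeline input under `outdir` and returns a manifest of
#' the files written with their MD5 digests.  Re-running with an identical
#' configuration reproduces identical files.
#'
#' @param config A [synth_config()] object.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a `data.frame` manifest (`file`, `md5`, `bytes`);
#'   also written as `manifest.json`.
#' @export
run_simulate <- function(config, outdir) {
  stopifnot(inherits(config, "synth_config"))
  ann <- generate_annotation(config)
  truth <- plant_truth(config, ann)
  peaks <- generate_peaksets(config, ann, truth)
  se <- generate_expression(config, truth)
  cohort <- generate_cohort(config)
  dose <- generate_dose_matrix(config)

  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  write_annotation(ann, file.path(outdir, "annotation.tsv"))
  for (cond in names(peaks))
    write_bed(peaks[[cond]],
              file.path(outdir, paste0(tolower(cond), ".bed")))
  write_expression(se, file.path(outdir, "expression.tsv"),
                   file.path(outdir, "sample_map.tsv"))
  write_cohort(cohort, file.path(outdir, "cohort.tsv"))
  write_dose_matrix(dose, file.path(outdir, "dose_matrix.csv"))
  write_gmt(cohort_gene_sets(config),
            file.path(outdir, "gene_sets.gmt"))
  jsonlite::write_json(
    list(gene_class = as.list(truth$gene_class),
         loss_transcripts = truth$loss_transcripts),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  paths <- file.path(outdir, files)
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(paths)),
                         bytes = unname(file.size(paths)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
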