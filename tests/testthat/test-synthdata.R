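small_cfg <- function(...) {
  synth_config(seed = 11, n_genes = 60, n_planted_cooperative = 6,
               n_planted_ezh2i_only = 4, n_planted_hdaci_only = 4,
               n_planted_additive = 4, genome_n_chroms = 2,
               chrom_length = 3e6, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(synth_config(n_genes = 0), "n_genes")
  expect_error(synth_config(n_genes = 10, n_planted_cooperative = 11),
               "exceed")
  expect_error(synth_config(censor_rate = 1), "censor_rate")
  expect_error(synth_config(hazard_ratio_atf3_low = 0), "hazard_ratio")
  expect_error(synth_config(dose_grid_a = c(1, 2)), "dose_grid_a")
  expect_error(synth_config(dose_grid_b = c(0, 2, 2)), "dose_grid_b")
})

test_that("annotation generation is deterministic, complete and sized", {
  cfg <- small_cfg()
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  expect_equal(length(unique(a1$gene_id)), cfg$n_genes)
  expect_true(all(a1$strand %in% c("+", "-")))
  expect_gte(mean(tapply(a1$biotype, a1$gene_id, `[`, 1) ==
                    "protein_coding"), 0.9)
  ## TSS of different genes on a chromosome are >= 3 halfwidths apart
  for (ch in unique(a1$chrom)) {
    tss <- sort(tapply(a1$tss, a1$gene_id, min)[
      unique(a1$gene_id[a1$chrom == ch])])
    if (length(tss) > 1)
      expect_true(all(diff(tss) >= 3 * cfg$tss_window_halfwidth))
  }
  expect_error(
    generate_annotation(synth_config(
      n_genes = 4, chrom_length = 1e4, tss_window_halfwidth = 1e4,
      n_planted_cooperative = 0, n_planted_ezh2i_only = 0,
      n_planted_hdaci_only = 0, n_planted_additive = 0)),
    "genome too small")
})

test_that("peak landscapes plant losses exactly at cooperative promoters", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg)
  truth <- plant_truth(cfg, ann)
  peaks <- generate_peaksets(cfg, ann, truth)
  expect_named(peaks, c("DMSO", "EZH2i", "HDACi", "Combo"))
  for (df in peaks) {
    expect_true(all(df$start < df$end))
    expect_true(!is.unsorted(order(df$chrom, df$start, df$end)))
  }
  ## independent interval scan: DMSO-only peaks inside windows flag the
  ## planted-loss transcripts (and possibly same-gene sibling
  ## transcripts whose windows overlap the same promoter peak), so at
  ## gene level the lost set is exactly the cooperative class
  w <- build_windows(ann, cfg$tss_window_halfwidth)
  lost <- oracle_call_lost(peaks$DMSO, peaks$EZH2i, w)
  expect_true(all(truth$loss_transcripts %in% w$transcript_id[lost]))
  coop <- names(truth$gene_class)[truth$gene_class == "cooperative_prc2"]
  expect_setequal(unique(w$gene_id[lost]), coop)
  expect_length(truth$loss_transcripts, cfg$n_planted_cooperative)
  ## HDACi matches DMSO at planted targets; same seed reproduces
  expect_identical(peaks, generate_peaksets(cfg, ann, truth))
  expect_identical(peaks$DMSO, peaks$HDACi)
})

test_that("planted expression effects follow the class design", {
  cfg0 <- small_cfg(noise_sd = 0)
  ann <- generate_annotation(cfg0)
  truth <- plant_truth(cfg0, ann)
  se <- generate_expression(cfg0, truth)
  mat <- SummarizedExperiment::assay(se)
  cond <- SummarizedExperiment::colData(se)$condition
  cm <- sapply(split(seq_along(cond), cond),
               function(i) rowMeans(mat[, i, drop = FALSE]))
  cls <- truth$gene_class
  eff <- cfg0$effect_log2fc
  coop <- names(cls)[cls == "cooperative_prc2"]
  expect_equal(unname(cm[coop, "Combo"] - cm[coop, "DMSO"]),
               rep(eff, length(coop)))
  expect_equal(unname(cm[coop, "EZH2i"] - cm[coop, "DMSO"]),
               rep(0, length(coop)))
  ez <- names(cls)[cls == "ezh2i_only"]
  expect_equal(unname(cm[ez, "EZH2i"] - cm[ez, "DMSO"]),
               rep(eff, length(ez)))
  expect_equal(unname(cm[ez, "Combo"] - cm[ez, "EZH2i"]),
               rep(0, length(ez)))
  expect_error(generate_expression(
    small_cfg(n_replicates_per_condition = 1), truth), "replicates")
})

test_that("residual noise has the configured scale", {
  cfg <- synth_config(seed = 3, n_genes = 5, n_planted_cooperative = 0,
                      n_planted_ezh2i_only = 0, n_planted_hdaci_only = 0,
                      n_planted_additive = 0,
                      n_replicates_per_condition = 2500,
                      genome_n_chroms = 1, chrom_length = 1e6,
                      noise_sd = 0.25)
  ann <- generate_annotation(cfg)
  se <- generate_expression(cfg, plant_truth(cfg, ann))
  x <- SummarizedExperiment::assay(se)[1, ]   # null gene, 10000 values
  expect_equal(sd(x), cfg$noise_sd, tolerance = 0.03)
})

test_that("cohort carries the planted gradient and survival law", {
  cfg <- small_cfg()
  co <- generate_cohort(cfg)
  mu <- tapply(co$EZH2, co$class, mean)
  expect_true(mu[["metastatic"]] > mu[["normal"]])
  am <- tapply(co$ATF3, co$class, mean)
  expect_true(am[["metastatic"]] < am[["normal"]])
  expect_true(all(co$time >= 0))
  expect_true(all(co$event %in% 0:1))

  ## exponential model: median time ratio across ATF3 arms ~ hazard ratio
  ratios <- sapply(1:50, function(s) {
    cfg2 <- synth_config(seed = s, cohort_n_normal = 0,
                         cohort_n_primary = 200,
                         cohort_n_metastatic = 200,
                         hazard_ratio_atf3_low = 3, censor_rate = 0)
    cc <- generate_cohort(cfg2)
    low <- attr(cc, "latent")$atf3_low
    median(cc$time[!low]) / median(cc$time[low])
  })
  expect_equal(mean(ratios), 3, tolerance = 0.2)
})

test_that("null hazard ratio gives uniform log-rank p-values", {
  pv <- sapply(1:100, function(s) {
    cfg <- synth_config(seed = s, cohort_n_normal = 0,
                        cohort_n_primary = 60, cohort_n_metastatic = 60,
                        hazard_ratio_atf3_low = 1, censor_rate = 0)
    cc <- generate_cohort(cfg)
    low <- attr(cc, "latent")$atf3_low
    logrank_test(cc$time[low], cc$event[low],
                 cc$time[!low], cc$event[!low])$p
  })
  expect_gt(mean(pv <= 0.05), 0.0)   # not degenerate at 0 everywhere
  expect_lt(mean(pv <= 0.05), 0.12)
  expect_gt(mean(pv), 0.35)          # roughly uniform mean ~ 0.5
})

test_that("dose matrix plants an exact HSA excess", {
  cfg <- small_cfg(planted_hsa_excess = 15)
  dm <- generate_dose_matrix(cfg)
  expect_equal(dm$response[1, 1], 0)
  expect_equal(hsa_score(dm)$score, 15)
  dm0 <- generate_dose_matrix(small_cfg(planted_hsa_excess = 0))
  expect_equal(hsa_score(dm0)$score, 0)
  ## single-agent margins are monotone saturating
  expect_true(all(diff(dm$response[, 1]) >= 0))
  expect_true(all(diff(dm$response[1, ]) >= 0))
})

test_that("run_simulate writes a reproducible, complete bundle", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- run_simulate(cfg, d1)
  m2 <- run_simulate(cfg, d2)
  expect_identical(m1$md5, m2$md5)
  expect_true(all(c("annotation.tsv", "dmso.bed", "ezh2i.bed",
                    "hdaci.bed", "combo.bed", "expression.tsv",
                    "sample_map.tsv", "cohort.tsv", "dose_matrix.csv",
                    "gene_sets.gmt", "truth.json") %in% m1$file))
  expect_true(file.exists(file.path(d1, "manifest.json")))
})
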