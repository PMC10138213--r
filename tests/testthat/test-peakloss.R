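ann1 <- function(tss, biotype = "protein_coding") {
  n <- length(tss)
  data.frame(transcript_id = paste0("T", seq_len(n)),
             gene_id = paste0("G", seq_len(n)),
             gene_name = paste0("G", seq_len(n)),
             chrom = "chr1", strand = "+", tss = tss,
             biotype = rep_len(biotype, n), stringsAsFactors = FALSE)
}

pk <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, name = ".",
             score = 0, strand = ".", stringsAsFactors = FALSE)
}

test_that("promoter windows are symmetric, clipped and filtered", {
  w <- build_windows(ann1(50000))
  expect_equal(c(w$start, w$end), c(40000, 60000))
  w <- build_windows(ann1(4000))
  expect_equal(c(w$start, w$end), c(0, 14000))   # clipped at 0
  ann <- ann1(c(5e4, 1e5, 1.5e5, 2e5, 2.5e5),
              biotype = c("protein_coding", "protein_coding",
                          "protein_coding", "noncoding", "noncoding"))
  expect_equal(nrow(build_windows(ann)), 3)
  expect_equal(nrow(build_windows(ann, protein_coding_only = FALSE)), 5)
  expect_warning(w0 <- build_windows(ann1(100, "noncoding")),
                 "no transcripts")
  expect_equal(nrow(w0), 0)
})

test_that("peak assignment uses half-open >= 1 bp overlap semantics", {
  w <- build_windows(ann1(50000))   # [40000, 60000)
  expect_equal(nrow(assign_peaks(w, pk(59999, 60050))), 1)  # 1 bp in
  expect_equal(nrow(assign_peaks(w, pk(60000, 60100))), 0)  # touching
  expect_equal(nrow(assign_peaks(w, pk(39000, 40000))), 0)  # touching
  ## one peak spanning two adjacent windows is assigned to both
  w2 <- build_windows(ann1(c(50000, 75000)))
  hits <- assign_peaks(w2, pk(59000, 66000))
  expect_setequal(hits$transcript_id, c("T1", "T2"))
  ## peaks on unknown chromosomes are ignored with a message
  expect_message(h <- assign_peaks(w, pk(100, 200, chrom = "chrUn")),
                 "ignored")
  expect_equal(nrow(h), 0)
})

test_that("lost-peak calling follows the any-overlap matching rule", {
  w <- build_windows(ann1(50000))
  r <- call_lost(pk(45000, 46000), pk(0, 1)[0, ], w)
  expect_true(r$transcripts$lost)
  expect_true(r$genes$lost)
  r <- call_lost(pk(45000, 46000), pk(45500, 47000), w)
  expect_false(r$transcripts$lost)
  ## empty control set: nothing can be lost
  r <- call_lost(pk(0, 1)[0, ], pk(45500, 47000), w)
  expect_false(any(r$genes$lost))
  ## gene flag is the OR over its transcripts
  ann <- ann1(c(50000, 90000))
  ann$gene_id <- ann$gene_name <- "G1"
  w2 <- build_windows(ann)
  r <- call_lost(pk(c(45000, 85000), c(46000, 86000)),
                 pk(45000, 46000), w2)
  expect_equal(r$transcripts$lost, c(FALSE, TRUE))
  expect_true(r$genes$lost)
})

test_that("lost-peak calling agrees with the all-pairs oracle", {
  set.seed(13)
  for (i in 1:100) {
    inst <- random_peakloss_instance()
    r <- call_lost(inst$control, inst$treated, inst$windows)
    expect_identical(r$transcripts$lost,
                     oracle_call_lost(inst$control, inst$treated,
                                      inst$windows))
  }
})

test_that("adding treated peaks never flips retained to lost", {
  set.seed(29)
  for (i in 1:25) {
    inst <- random_peakloss_instance()
    before <- call_lost(inst$control, inst$treated,
                        inst$windows)$transcripts$lost
    extra <- inst$control[sample(nrow(inst$control),
                                 min(3, nrow(inst$control))), ,
                          drop = FALSE]
    after <- call_lost(inst$control, rbind(inst$treated, extra),
                       inst$windows)$transcripts$lost
    expect_true(all(after <= before))
  }
})

test_that("identical conditions flag no losses", {
  set.seed(31)
  for (i in 1:10) {
    inst <- random_peakloss_instance()
    r <- call_lost(inst$control, inst$control, inst$windows)
    expect_false(any(r$transcripts$lost))
  }
})

test_that("PRC2 target extraction returns lost genes sorted", {
  w <- build_windows(ann1(c(50000, 100000)))
  r <- call_lost(pk(c(45000, 95000), c(46000, 96000)),
                 pk(95000, 96000), w)
  expect_equal(prc2_target_genes(r), "G1")
  f <- withr::local_tempfile()
  prc2_target_genes(r, f)
  expect_equal(readLines(f), "G1")
  r0 <- call_lost(pk(0, 1)[0, ], pk(0, 1)[0, ], w)
  expect_equal(prc2_target_genes(r0), character())
})

test_that("planted losses are recovered exactly on the synthetic genome", {
  cfg <- synth_config(seed = 3, n_genes = 120,
                      n_planted_cooperative = 10,
                      n_planted_ezh2i_only = 5,
                      n_planted_hdaci_only = 5, n_planted_additive = 5,
                      genome_n_chroms = 2, chrom_length = 4e6)
  ann <- generate_annotation(cfg)
  truth <- plant_truth(cfg, ann)
  peaks <- generate_peaksets(cfg, ann, truth)
  w <- build_windows(ann)
  r <- call_lost(peaks$DMSO, peaks$EZH2i, w)
  coop <- names(truth$gene_class)[truth$gene_class ==
                                    "cooperative_prc2"]
  expect_setequal(prc2_target_genes(r), coop)
})
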