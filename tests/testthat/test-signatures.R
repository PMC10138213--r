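test_that("ssGSEA reproduces the hand-computed ECDF walk", {
  ## N = 3, S = {g1}, alpha = 0: (1-0) + (1-1/2) + (1-1) = 1.5
  expect_equal(ssgsea_score(c(g1 = 3, g2 = 2, g3 = 1), "g1",
                            alpha = 0), 1.5)
  ## rank invariance: adding a constant leaves the score unchanged
  set.seed(1)
  x <- setNames(rnorm(20), paste0("g", 1:20))
  s <- gene_set("S", "", paste0("g", c(2, 5, 9)))
  expect_equal(ssgsea_score(x + 100, s), ssgsea_score(x, s))
  ## identical rankings give identical scores
  expect_equal(ssgsea_score(2 * x, s), ssgsea_score(x, s))
  ## score bounded by N
  expect_lt(abs(ssgsea_score(x, s)), length(x))
  expect_error(ssgsea_score(x, c("zz")), "no member")
  expect_error(ssgsea_score(x, names(x)), "universe")
})

test_that("ssGSEA agrees with the brute-force oracle", {
  set.seed(101)
  for (i in 1:100) {
    N <- sample(5:50, 1)
    expr <- setNames(rnorm(N), paste0("g", 1:N))
    k <- sample(1:(N - 1), 1)
    members <- sample(names(expr), k)
    alpha <- sample(c(0, 0.25, 0.75, 1), 1)
    expect_lt(abs(ssgsea_score(expr, members, alpha) -
                    oracle_ssgsea(expr, members, alpha)), 1e-9)
  }
})

test_that("signature z-scoring is the standard sample standardization", {
  expect_equal(zscore_signature(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  z <- zscore_signature(rnorm(50, 10, 3))
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_error(zscore_signature(c(5, 5)), "SD = 0|constant")
  expect_error(zscore_signature(3), ">= 2")
})

test_that("classic GSEA running sum matches hand computation", {
  ## S = top-1 of 3, metrics {2,1,1}, weight 1: running {1, .5, 0}
  expect_equal(gsea_es(c(a = 2, b = 1, c = 1), "a"), 1)
  ## with weight 0 the ES lies in [-1, 1]
  set.seed(3)
  x <- setNames(rnorm(30), paste0("g", 1:30))
  es0 <- gsea_es(x, paste0("g", 1:5), weight = 0)
  expect_lte(abs(es0), 1)
  ## a set covering all but one bottom gene scores positive
  nm <- names(sort(x, decreasing = TRUE))
  expect_gt(gsea_es(x, nm[1:29]), 0)
  ## reversing the ranking flips the ES sign for a top-concentrated set
  top <- nm[1:5]
  expect_gt(gsea_es(x, top, weight = 0), 0)
  expect_lt(gsea_es(-x, top, weight = 0), 0)
  expect_error(gsea_es(c(a = 0, b = 1), "a"), "zero")
})

test_that("permutation GSEA is deterministic and detects planted shifts", {
  set.seed(4)
  mat <- matrix(rnorm(100 * 8), 100, 8,
                dimnames = list(paste0("g", 1:100), NULL))
  groups <- rep(c("T", "C"), each = 4)
  set <- gene_set("S", "", paste0("g", 1:12))
  r1 <- gsea_permutation(mat, groups, set, n_perm = 99, seed = 5)
  r2 <- gsea_permutation(mat, groups, set, n_perm = 99, seed = 5)
  expect_equal(r1$p_perm, r2$p_perm)
  expect_error(gsea_permutation(mat, groups, set, n_perm = 5), "n_perm")

  ## planted +2 SD shift of the set genes in class T
  mat2 <- mat
  mat2[1:12, 1:4] <- mat2[1:12, 1:4] + 2
  r <- gsea_permutation(mat2, factor(groups, levels = c("T", "C")), set,
                        n_perm = 999, seed = 6)
  expect_gt(r$es, 0)
  expect_equal(r$p_perm, 1 / 1000)   # minimum attainable at n_perm=999
  expect_gt(r$nes, 1)
})

test_that("signature correlation recovers the planted coupling", {
  expect_equal(correlate_signatures(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(correlate_signatures(c(1, 2, 3), c(-1, -2, -3))$r, -1)
  expect_error(correlate_signatures(1:3, 1:4), "length")
  expect_error(correlate_signatures(1:3, c(2, 2, 2)), "variance")

  sets <- cohort_gene_sets(synth_config())
  gene_cols <- function(co) {
    m <- t(as.matrix(co[, grep("^(ET|AT|BG)", names(co))]))
    colnames(m) <- co$sample
    m
  }
  run_cohort <- function(s, rho) {
    cfg <- synth_config(seed = s, cohort_n_normal = 0,
                        cohort_n_primary = 75,
                        cohort_n_metastatic = 75,
                        signature_coupling = rho)
    m <- gene_cols(generate_cohort(cfg))
    zA <- zscore_signature(ssgsea_matrix(m, sets$PRC2_DEREPRESSION))
    zB <- zscore_signature(ssgsea_matrix(m, sets$ATF3_ACTIVITY))
    correlate_signatures(zA, zB)$r
  }
  ## rank-based scores are grade transforms of the latent activities, so
  ## the recoverable Pearson correlation for a planted Gaussian coupling
  ## rho is the closed-form grade correlation (6/pi) asin(rho/2), not
  ## rho itself (0.684 at rho = 0.7)
  rs <- sapply(1:30, run_cohort, rho = 0.7)
  expect_equal(mean(rs), 6 / pi * asin(0.7 / 2), tolerance = 0.08)
  ## and an uncoupled cohort shows no signature correlation
  r0 <- sapply(1:10, run_cohort, rho = 0)
  expect_lt(abs(mean(r0)), 0.1)
})
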