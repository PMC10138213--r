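---
title: "Discovering cooperatively derepressed PRC2 targets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cooperatively derepressed PRC2 targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicoop)
```

## The scientific problem

The Polycomb Repressive Complex 2 (PRC2), through its catalytic subunit
EZH2, silences genes by trimethylating histone H3 lysine 27 (H3K27me3).
Histone deacetylases (HDACs) reinforce that silencing by removing the
activating H3K27ac mark from the same residue.  A consequence is that a
subset of PRC2 target genes cannot be reactivated by EZH2 inhibition
alone: removing the methyl mark is necessary but not sufficient if
acetylation is still suppressed.  In castration-resistant prostate
cancer, combined EZH2/HDAC inhibition derepresses such genes — notably
the stress-response transcription factor *ATF3* — and that derepression
drives the therapeutic response.

`epicoop` implements the computational side of this biology as a tested,
reusable pipeline:

1. **Cooperative induction** (`contrast()`, `select_cooperative()`):
   genes significantly induced by the drug combination relative to *all
   three* other arms (vehicle and both single agents).
2. **Promoter demethylation** (`build_windows()`, `call_lost()`,
   `prc2_target_genes()`): genes whose transcription start site (TSS)
   windows lose at least one H3K27me3 peak under EZH2 inhibition.
3. **Candidate nomination** (`intersect_candidates()`,
   `run_discovery()`): the intersection of the two sets — genes that are
   both demethylated and combination-specifically induced.

Downstream modules quantify signature activity per sample (ssGSEA,
classic GSEA with a permutation null), stratify tumor cohorts and
estimate survival (Kaplan–Meier, log-rank), and score drug synergy
against the highest-single-agent (HSA) reference.

## Differential expression model

Input is a normalized log2 expression matrix (microarray-like) with a
sample-to-condition map over the four arms DMSO, EZH2i, HDACi, Combo.
Per gene, `contrast()` reports

* `log2fc` — treatment mean minus reference mean on the log2 scale;
* `p` — two-sided pooled-variance two-sample Student *t* p-value with
  `n1 + n2 - 2` degrees of freedom;
* `q` — Benjamini–Hochberg step-up adjustment computed per contrast over
  the full gene universe of the matrix (no independent filtering).

**Why the pooled t rather than Welch.**  With 2–3 replicates per arm the
Welch–Satterthwaite degrees of freedom collapse toward 2, and no
attainable p-value survives BH correction reliably: at the reference
study conditions (effect 2.0 log2, residual SD 0.25, 3 replicates,
1,000 genes) per-contrast sensitivity is ~0.61 under Welch versus ~0.97
under the pooled test.  Replicate arms of a single array experiment are
reasonably homoscedastic, and the pooled test is the standard
small-replicate choice when empirical-Bayes moderation is out of scope
(moderated variance models are deliberately not implemented here).

**Degenerate cases.**  Zero variance in both groups is possible in
noiseless simulation fixtures.  Convention: equal means give `p = 1`;
unequal means give the smallest positive double, so planted noiseless
effects always clear any fixed threshold deterministically.

**Thresholds.**  Induction means `log2fc > 1` **and** `q < 0.05`, both
strict, and *cooperative* induction requires this in all three contrasts
Combo-vs-DMSO, Combo-vs-HDACi and Combo-vs-EZH2i.  A gene induced
equally by one single agent and the combination has `log2fc ~ 0` in the
corresponding Combo-vs-single-agent contrast and is excluded — this is
the operational meaning of "unique to the combination".

## Peak-loss model

Promoter windows are symmetric, strand-blind intervals
`[TSS - W, TSS + W)` with `W = 10000` bp (a 20-kb window), clipped at
coordinate 0, built for protein-coding transcripts only by default.  All
coordinates are 0-based half-open (BED semantics) end to end; touching
intervals do not overlap; any shared base pair (>= 1 bp) is an overlap.
Overlap queries are evaluated with `GenomicRanges::findOverlaps()` after
shifting to 1-based closed coordinates; an exhaustive all-pairs checker
in the test suite guards the conversion.

A control-condition peak assigned to a window is **lost** when no
treated-condition peak overlaps it by at least 1 bp.  The matching rule
is deliberately the simplest one consistent with default-parameter
interval intersection — no reciprocal-overlap fraction, no peak-score
threshold, no peak-identity matching across conditions.  A transcript is
lost when at least one of its in-window control peaks is lost; a gene is
lost when at least one of its transcripts is.  Lost-gene sets under
EZH2i-vs-DMSO define the PRC2 target genes.

Two structural properties follow and are tested: adding treated peaks
can only flip lost to retained (monotonicity), and comparing a peak set
against itself flags nothing.

## The synthetic study generator

`synth_config()` fixes every study condition in one validated object;
all generators derive independent named RNG substreams from the single
master seed, so regenerating one input never perturbs another, and
identical configurations give byte-identical files.

* **Annotation**: gene TSS spaced at least `3 W` apart (slot pitch `4 W`
  minus jitter `< W`), so no promoter window can capture a neighbor's
  peaks and planted truth is unambiguous; one or two transcripts per
  gene (alternative TSS within 500 bp); 5% noncoding genes exercise the
  biotype filter.  Default genome: 4 chromosomes of 12 Mb, which holds
  the default 1,000 genes with headroom.
* **Gene classes**: 30 `cooperative_prc2`, 20 `additive`, 20
  `ezh2i_only`, 20 `hdaci_only`, remainder `null`.  Cooperative and
  additive genes are elevated by `effect_log2fc = 2` in Combo only;
  single-agent classes are elevated in their agent *and* in Combo (so
  they fail the unique-to-combo contrasts); cooperative genes are never
  elevated by a single agent.  Replicates default to 3 per arm — the
  replicate count is not derivable from the emulated design and 3 is the
  conventional array-arm size.  Noise is Gaussian on the log2 scale
  (microarray-like, matching the t-contrast model), SD 0.25;
  `noise_sd = 0` is allowed so noiseless fixtures recover planted
  effects exactly.
* **Peak landscapes**: one 2-kb H3K27me3 peak at each cooperative gene's
  planted transcript in DMSO and HDACi, absent from EZH2i and Combo;
  stable promoter peaks at 20% of non-cooperative transcripts and ~200
  intergenic background peaks (placed `1.4 W` downstream of a TSS, which
  the `>= 3 W` spacing guarantees is outside every window) appear in all
  four conditions.  Additive-class genes get no peak loss — the
  candidate intersection is what removes them, reproducing the logic
  that candidates must be both induced and demethylated.
* **Cohort**: tissue classes sized 28 normal / 59 primary / 35
  metastatic, the class structure of the public cohort the analysis
  emulates.  EZH2 marker expression shifts by +2 SD (primary) and +4.4
  SD (metastatic) relative to normal; `pnorm(4.4 - 3) = 0.92` so about
  92% of metastatic samples sit >= 3 SD above the normal mean by
  construction.  ATF3 decreases along the same gradient.  Two disjoint
  25-gene signatures (PRC2-derepression and ATF3-activity analogues) are
  driven by latent per-sample activities with correlation
  `signature_coupling = 0.7`, embedded in a 950-gene universe in which
  every gene carries its own baseline log2 intensity drawn from U(4, 10).
  The baseline spread matters: rank-based scores over a small
  single-baseline universe saturate (all signature genes sweep the list
  together) and disjoint sets become compositionally anti-correlated,
  which biases cohort-level score correlations far below the planted
  coupling.  With transcriptome-like baselines, latent shifts move ranks
  locally and the recoverable Pearson correlation approaches its
  theoretical ceiling for grade-transformed Gaussian latents,
  `(6/pi) * asin(rho/2) = 0.684` at `rho = 0.7` — the value the test
  suite checks against, since a rank-based scorer cannot recover `rho`
  itself.
* **Survival**: exponential times (baseline median 60 time units) with
  the hazard multiplied by `hazard_ratio_atf3_low = 3` for samples with
  below-median latent ATF3 activity; independent censoring replaces a
  `censor_rate = 0.3` fraction of times with a uniform fraction of the
  true time.  The exponential model is the simplest with a closed-form
  median (`ln 2 / lambda`), which the tests exploit.
* **Dose matrix**: Emax single-agent curves on the dose grids
  0/1.25/2.5/5/10 and 0/0.5/1/2/4/8 (the emulated viability assay's
  series), with every both-positive-dose well equal to its HSA reference
  plus exactly `planted_hsa_excess = 15` points.  The surface is
  deterministic so the planted excess is recovered exactly.

What the generator does *not* emulate: probe-level array artifacts,
count-based RNA-seq noise, chromatin domain structure, peak-calling
uncertainty, correlated gene-gene expression modules, or non-proportional
hazards.  Passing tests therefore demonstrate correctness of the
pipeline's logic under its stated model, not robustness to those
real-data complications.

## Enrichment scoring

`ssgsea_score()` ranks one sample's genes descending (ties broken by
stable input order) and integrates the difference between a weighted
in-set ECDF and the unweighted out-of-set ECDF.  The weight of an in-set
gene is its expression rank from the bottom (the top gene carries rank
N) raised to `alpha = 0.75`, so highly expressed members dominate.  No
cross-set range normalization is applied because scores are z-scored per
signature across samples immediately afterwards (`zscore_signature()`),
which makes any linear rescaling a no-op.

`gsea_permutation()` ranks genes by the signal-to-noise metric
`(mu1 - mu2) / (sigma1 + sigma2)` with each SD floored at `0.2 |mu|`
(0.2 when the mean is zero), computes the classic running-sum ES, and
draws the null from random same-size gene sets.  Gene-set permutation is
used because the emulated designs have too few samples per arm for
phenotype permutation.  The p-value is two-sided on the ES magnitude
over all null sets, `p = (1 + #{|ES_0| >= |ES|}) / (n_perm + 1)` — this
makes p uniformly distributed under a true null (verified by a
calibration simulation in the tests), whereas restricting the count to
same-sign nulls would roughly double the type-I error.  The same-sign
restriction is retained only where it belongs, in the NES normalization
`ES / mean(|ES_0| of the same sign)`.

## Cohort and survival conventions

* `zscore_vs_reference()` standardizes all samples by the reference
  (normal-tissue) class's mean and *sample* SD (n − 1); the tail
  fraction at `z >= 3` is inclusive at the boundary.
* `stratify_deciles()` takes exactly `floor(0.10 n)` samples per tail
  and breaks ties by sample id, making membership deterministic and
  size-stable.
* `km_estimate()`/`logrank_test()` delegate to the `survival` package
  (the field standard) behind a minimal product-limit/log-rank surface;
  the tests verify them against hand-tabulated product-limit and O/E/V
  computations.  The log-rank test is the conventional choice for
  comparing Kaplan–Meier strata when no test is otherwise specified.

## Synergy conventions

Responses are % inhibition relative to vehicle,
`100 (1 - raw/vehicle)`, unclipped (stimulation stays negative).  The
HSA reference at a combination well is the better single-agent response
at the same doses; the score is the mean excess over wells with both
doses positive — margin wells have zero excess by definition and would
only dilute the average.  Replicate surfaces are averaged well-wise
before scoring.  A score strictly above 10 points is called synergistic.

## Numerical and degenerate-input choices

* Ranking ties everywhere break by stable input order (documented
  determinism rather than random tie-breaks).
* `call_lost()` with an empty control set flags nothing; empty
  annotations yield empty window sets with a warning.
* BH adjustment, interval overlap and ssGSEA each have an independent
  brute-force oracle in the test suite (hand step-up, all-pairs scan,
  double-loop ECDF walk) checked over 100 random instances.
* All validation failures name the offending line, sample, gene or
  parameter.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on generated
data: the discovery pipeline at 1,000 genes x 12 samples with the
default planted classes (about 10 s end to end); oracle equivalence on
100 random instances of up to 50 genes/intervals; permutation
calibration with 200 repetitions of 199 null sets over a 300-gene
universe; log-rank calibration over 500 simulated pairs of 50-sample
arms; and cohort analyses at 122–150 samples over a 950-gene universe.
These sizes keep a full run to a few minutes while leaving the
Monte-Carlo slack of each check well below its tolerance.

## Known limitations

* Gene identity is the case-sensitive symbol string; no alias or
  probe-to-gene resolution is attempted.
* The peak-matching rule is any-overlap; analyses sensitive to partial
  peak splitting/merging would need a reciprocal-overlap variant.
* Signature correlations recovered from rank-based scores are bounded
  by the grade-correlation ceiling discussed above; they are estimates
  of a monotone association, not of the latent Pearson coefficient.
* Survival analysis is limited to two-group product-limit comparison;
  no Cox regression or covariate adjustment.
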