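## Cohort stratification and survival analysis: z-scores against a
## reference tissue class, tail fractions, decile stratification,
## Kaplan-Meier product-limit estimates and the log-rank test.

#' Z-score a gene's expression against a reference tissue class
#'
#' `z_i = (x_i - mean_ref) / SD_ref`, using the reference class's mean
#' and sample SD (n - 1 denominator), computed for *all* samples
#' including the reference class itself.  Invariant to positive affine
#' rescaling of the expression values.
#'
#' @param cohort Cohort `data.frame` (see [read_cohort()]).
#' @param gene Gene column name.
#' @param reference_class Tissue class to standardize against (default
#'   `"normal"`; needs >= 2 samples and nonzero SD).
#' @return Named numeric vector of z-scores (names = sample ids).
#' @export
zscore_vs_reference <- function(cohort, gene,
                                reference_class = "normal") {
  if (!gene %in% names(cohort))
    stop("gene '", gene, "' not in cohort table", call. = FALSE)
  ref <- cohort[[gene]][cohort$class == reference_class]
  if (length(ref) < 2L)
    stop("reference class '", reference_class,
         "' has fewer than 2 samples", call. = FALSE)
  s <- sd(ref)
  if (s == 0)
    stop("reference class has zero SD for gene '", gene, "'",
         call. = FALSE)
  setNames((cohort[[gene]] - mean(ref)) / s, cohort$sample)
}

#' Fraction of samples at or above a z-score threshold
#'
#' Inclusive at the boundary (`z >= threshold`), matching the convention
#' "expressed at levels >= 3 SD above normal".
#'
#' @param z Numeric z-score vector (typically restricted to one tissue
#'   class).
#' @param threshold Z threshold (default 3).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_above <- function(z, threshold = 3) {
  if (length(z) == 0L) stop("empty class", call. = FALSE)
  mean(z >= threshold)
}

#' Stratify a cohort into top and bottom expression deciles
#'
#' High = the `floor(decile * n)` samples with the largest values, low =
#' the same number with the smallest.  Ties are broken deterministically
#' by sample id.
#'
#' @param values Named numeric vector (names = sample ids) of expression
#'   or signature scores; `n >= 10`.
#' @param decile Fraction per tail (default 0.10).
#' @return A list with character vectors `high` and `low`.
#' @export
stratify_deciles <- function(values, decile = 0.10) {
  stopifnot(is.numeric(values), !is.null(names(values)),
            decile > 0, decile < 0.5)
  n <- length(values)
  k <- floor(decile * n)
  if (n < 10L || k < 1L)
    stop("need >= 10 samples for decile stratification", call. = FALSE)
  ids <- names(values)
  hi_ord <- order(-values, ids)
  lo_ord <- order(values, ids)
  list(high = ids[hi_ord[seq_len(k)]], low = ids[lo_ord[seq_len(k)]])
}

#' Kaplan-Meier product-limit survival estimate
#'
#' At each distinct event time with `d` events among `n` at risk the
#' survival estimate multiplies by `(1 - d/n)`; censored times reduce the
#' risk set only.  With no censoring the estimate equals the empirical
#' survival function.
#'
#' @param times Nonnegative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return A `data.frame` of class `survival_curve` with one row per
#'   distinct event time: `time`, `n_risk`, `n_event`, `surv`.
#' @examples
#' km_estimate(1:4, rep(1, 4))$surv  # 0.75 0.50 0.25 0.00
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events))
    stop("times and events differ in length", call. = FALSE)
  if (any(times < 0))
    stop("negative survival time", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep],
                    n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep],
                    surv = fit$surv[keep],
                    row.names = NULL)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each event time the observed minus expected
#' events in group A are accumulated with the hypergeometric variance;
#' the statistic `(sum(O - E))^2 / sum(V)` is referred to a chi-square
#' distribution with 1 df.  Symmetric in group order.
#'
#' @param times_a,events_a Follow-up times and event indicators, group A.
#' @param times_b,events_b Same for group B.
#' @return A list: `statistic` (chi-square), `p` (two-sided), `n`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  if (sum(events_a) + sum(events_b) == 0)
    stop("no events in either group; log-rank undefined", call. = FALSE)
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  d <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- d$chisq
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       n = length(time))
}
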