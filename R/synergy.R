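## Dose-matrix normalization and highest-single-agent (HSA, Gaddum
## non-interaction) synergy scoring.

#' Construct a dose-response matrix
#'
#' @param doses_a,doses_b Increasing dose sequences including 0.
#' @param response Numeric matrix of % inhibition relative to vehicle,
#'   rows = `doses_a`, columns = `doses_b`; the grid must be complete.
#'   Rows/columns are reordered canonically if the grids arrive unsorted.
#' @return An object of class `dose_response`.
#' @export
dose_response <- function(doses_a, doses_b, response) {
  doses_a <- as.numeric(doses_a)
  doses_b <- as.numeric(doses_b)
  response <- as.matrix(response)
  if (nrow(response) != length(doses_a) ||
      ncol(response) != length(doses_b))
    stop("response matrix does not match the dose grids", call. = FALSE)
  if (any(is.na(response)))
    stop("dose grid is incomplete (missing wells)", call. = FALSE)
  oa <- order(doses_a); ob <- order(doses_b)
  doses_a <- doses_a[oa]; doses_b <- doses_b[ob]
  response <- response[oa, ob, drop = FALSE]
  if (anyDuplicated(doses_a) || anyDuplicated(doses_b))
    stop("duplicate doses in a grid", call. = FALSE)
  if (doses_a[1] != 0 || doses_b[1] != 0)
    stop("dose grids must include 0 (vehicle)", call. = FALSE)
  dimnames(response) <- list(doses_a, doses_b)
  structure(list(doses_a = doses_a, doses_b = doses_b,
                 response = response), class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("Dose-response matrix: ", length(x$doses_a), " x ",
      length(x$doses_b), " wells (% inhibition)\n", sep = "")
  print(round(x$response, 2))
  invisible(x)
}

#' Normalize raw viability to % inhibition relative to vehicle
#'
#' `% inhibition = 100 * (1 - raw / vehicle)`; the vehicle well maps to
#' exactly 0.  Negative inhibition (stimulation) is preserved, not
#' clipped.
#'
#' @param raw Numeric matrix of raw viability (e.g. luminescence), rows
#'   indexed by `doses_a`, columns by `doses_b`.
#' @param doses_a,doses_b Dose grids including 0.
#' @return A [dose_response()] object.
#' @export
normalize_viability <- function(raw, doses_a, doses_b) {
  raw <- as.matrix(raw)
  ia <- which(as.numeric(doses_a) == 0)
  ib <- which(as.numeric(doses_b) == 0)
  if (length(ia) != 1L || length(ib) != 1L)
    stop("dose grids must contain a single vehicle (0) entry",
         call. = FALSE)
  vehicle <- raw[ia, ib]
  if (!is.finite(vehicle) || vehicle <= 0)
    stop("vehicle signal must be positive", call. = FALSE)
  dose_response(doses_a, doses_b, 100 * (1 - raw / vehicle))
}

#' HSA (highest-single-agent) synergy score
#'
#' For every well with both doses positive the HSA reference is the
#' better of the two single-agent responses at the same doses,
#' `max(response(a, 0), response(0, b))`; the excess is the observed
#' response minus the reference, and the synergy score is the mean excess
#' over all such wells.  Margin wells (either dose 0) define the
#' reference and are excluded from the average.
#'
#' @param dose A [dose_response()] object with complete single-agent
#'   margins.
#' @return A list of class `synergy_result`: `reference` and `excess`
#'   matrices over the positive-dose grid, `score` (mean excess,
#'   percentage points) and `synergistic` (`score > 10`).
#' @examples
#' d <- dose_response(c(0, 1), c(0, 1),
#'                    matrix(c(0, 20, 30, 45), 2, 2))
#' hsa_score(d)$score  # 45 - max(20, 30) = 15
#' @export
hsa_score <- function(dose) {
  stopifnot(inherits(dose, "dose_response"))
  pa <- which(dose$doses_a > 0)
  pb <- which(dose$doses_b > 0)
  if (length(pa) == 0L || length(pb) == 0L)
    stop("missing single-agent margin (need doses > 0 on both axes)",
         call. = FALSE)
  single_a <- dose$response[pa, 1]
  single_b <- dose$response[1, pb]
  reference <- outer(single_a, single_b, pmax)
  observed <- dose$response[pa, pb, drop = FALSE]
  excess <- observed - reference
  dimnames(reference) <- dimnames(excess) <-
    list(dose$doses_a[pa], dose$doses_b[pb])
  structure(list(reference = reference, excess = excess,
                 score = mean(excess), synergistic = mean(excess) > 10),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("HSA synergy score: ", round(x$score, 2), " (",
      if (x$synergistic) "synergistic, score > 10"
      else "not synergistic", ")\n", sep = "")
  invisible(x)
}

#' Classify a synergy result
#'
#' Synergistic iff the score strictly exceeds the threshold (a score of
#' exactly 10 is not called synergistic).
#'
#' @param result A `synergy_result` from [hsa_score()].
#' @param threshold Score threshold (default 10 percentage points).
#' @return Logical flag.
#' @export
classify_synergy <- function(result, threshold = 10) {
  stopifnot(inherits(result, "synergy_result"))
  result$score > threshold
}

#' Average replicate dose-response matrices well-wise
#'
#' @param doses List of [dose_response()] objects on identical grids.
#' @return A single [dose_response()] with the well-wise mean response.
#' @export
average_replicates <- function(doses) {
  stopifnot(length(doses) >= 1L,
            all(vapply(doses, inherits, logical(1), "dose_response")))
  ref <- doses[[1]]
  for (d in doses[-1]) {
    if (!identical(d$doses_a, ref$doses_a) ||
        !identical(d$doses_b, ref$doses_b))
      stop("replicate matrices are on different dose grids",
           call. = FALSE)
  }
  avg <- Reduce(`+`, lapply(doses, `[[`, "response")) / length(doses)
  dose_response(ref$doses_a, ref$doses_b, avg)
}
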