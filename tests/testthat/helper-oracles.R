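## Independent brute-force oracles, deliberately coded without reusing
## any package internals, used to cross-check the fast implementations.

## ssGSEA as a literal double-loop ECDF walk.  Expression ranks are taken
## from the bottom (top gene has rank N) and raised to alpha.
oracle_ssgsea <- function(expr, members, alpha) {
  N <- length(expr)
  nm <- names(expr)[order(-expr)]
  inset <- nm %in% members
  denom <- 0
  for (i in seq_len(N))
    if (inset[i]) denom <- denom + (N - i + 1)^alpha
  n_out <- sum(!inset)
  score <- 0
  cum_in <- 0
  cum_out <- 0
  for (i in seq_len(N)) {
    if (inset[i]) cum_in <- cum_in + (N - i + 1)^alpha
    else cum_out <- cum_out + 1
    score <- score + (cum_in / denom - cum_out / n_out)
  }
  score
}

## Lost-peak calling by exhaustive all-pairs interval checks
## (0-based half-open: overlap iff start1 < end2 and start2 < end1).
oracle_call_lost <- function(control, treated, windows) {
  ovl <- function(c1, s1, e1, c2, s2, e2)
    c1 == c2 && s1 < e2 && s2 < e1
  lost <- logical(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    for (i in seq_len(nrow(control))) {
      if (!ovl(control$chrom[i], control$start[i], control$end[i],
               windows$chrom[w], windows$start[w], windows$end[w]))
        next
      matched <- FALSE
      for (j in seq_len(nrow(treated))) {
        if (ovl(control$chrom[i], control$start[i], control$end[i],
                treated$chrom[j], treated$start[j], treated$end[j])) {
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        lost[w] <- TRUE
        break
      }
    }
  }
  lost
}

## Benjamini-Hochberg by the literal step-up recursion.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    q[o[i]] <- running
  }
  pmin(q, 1)
}

## Two-group log-rank chi-square by hand-tabulated O/E/V at event times.
oracle_logrank <- function(ta, ea, tb, eb) {
  tm <- c(ta, tb)
  ev <- c(ea, eb)
  g <- rep(1:2, c(length(ta), length(tb)))
  times <- sort(unique(tm[ev == 1]))
  O <- 0; E <- 0; V <- 0
  for (tt in times) {
    nA <- sum(tm >= tt & g == 1)
    nB <- sum(tm >= tt & g == 2)
    n <- nA + nB
    dA <- sum(tm == tt & ev == 1 & g == 1)
    d <- sum(tm == tt & ev == 1)
    O <- O + dA
    E <- E + d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (nB / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

## Random small peak-loss instance shared by oracle and property tests.
random_peakloss_instance <- function() {
  n_win <- sample(1:6, 1)
  windows <- data.frame(
    transcript_id = paste0("T", seq_len(n_win)),
    gene_id = paste0("G", seq_len(n_win)),
    chrom = sample(c("chr1", "chr2"), n_win, replace = TRUE),
    start = sample(0:400, n_win, replace = TRUE),
    stringsAsFactors = FALSE)
  windows$end <- windows$start + sample(50:300, n_win, replace = TRUE)
  rnd_peaks <- function(n) {
    s <- sample(0:600, n, replace = TRUE)
    data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
               start = s, end = s + sample(10:150, n, replace = TRUE),
               name = rep(".", n), score = rep(0, n),
               strand = rep(".", n), stringsAsFactors = FALSE)
  }
  list(windows = windows,
       control = rnd_peaks(sample(0:25, 1)),
       treated = rnd_peaks(sample(0:25, 1)))
}
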