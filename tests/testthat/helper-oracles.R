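# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (exhaustive enumeration,
# closed forms, Lance-Williams recurrences) so agreement is evidence, not
# tautology.

# exhaustive sliding-window motif scan: checks every length-5 window
oracleScanCXXCH <- function(sequence) {
  ch <- strsplit(sequence, "")[[1L]]
  n <- length(ch)
  hits <- integer()
  if (n >= 5L) for (i in seq_len(n - 4L)) {
    if (ch[i] == "C" && ch[i + 3L] == "C" && ch[i + 4L] == "H")
      hits <- c(hits, i - 1L)  # 0-based
  }
  hits
}

# closed-form OLS slope
oracleOLSSlope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# brute-force global alignment with affine gaps by recursive enumeration
# of the full alignment space; Biostrings convention: a gap run of length
# L costs gapOpening + L * gapExtension
oracleGlobalAlignScore <- function(a, b, submat, gapOpen, gapExt) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  memo <- new.env(hash = TRUE)
  # state: (i, j, inGapA, inGapB) -> best score aligning a[i..], b[j..]
  rec <- function(i, j, gapA, gapB) {
    key <- paste(i, j, gapA, gapB)
    if (!is.null(memo[[key]])) return(memo[[key]])
    na <- length(av); nb <- length(bv)
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb)
      best <- max(best, submat[av[i], bv[j]] + rec(i + 1L, j + 1L, FALSE,
                                                   FALSE))
    if (i <= na)  # a[i] against gap in b
      best <- max(best,
                  -(if (gapB) 0 else gapOpen) - gapExt +
                    rec(i + 1L, j, FALSE, TRUE))
    if (j <= nb)  # gap in a against b[j]
      best <- max(best,
                  -(if (gapA) 0 else gapOpen) - gapExt +
                    rec(i, j + 1L, TRUE, FALSE))
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, FALSE, FALSE)
}

# brute-force ward.D2 agglomeration: Lance-Williams on squared Euclidean
# dissimilarities, every merge candidate evaluated, heights = sqrt
oracleWardD2 <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  sizes <- rep(1L, n)
  active <- seq_len(n)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); bestval <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii >= jj) next
      i <- active[ii]; j <- active[jj]
      if (d2[i, j] < bestval) { bestval <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    heights[step] <- sqrt(bestval)
    for (k in setdiff(active, c(i, j))) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# hand evaluation of the RBH definition on an explicit score table
oracleRBH <- function(S) {
  pairs <- list()
  for (a in rownames(S)) {
    b <- sort(colnames(S)[S[a, ] == max(S[a, ])])[1L]
    a2 <- sort(rownames(S)[S[, b] == max(S[, b])])[1L]
    if (identical(a2, a)) pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  do.call(rbind, pairs)
}

# sort-based median flag oracle
oracleHighFlags <- function(tpm) {
  s <- sort(tpm)
  n <- length(s)
  med <- if (n %% 2L == 1L) s[(n + 1L) / 2L]
         else mean(s[c(n / 2L, n / 2L + 1L)])
  tpm > med
}
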