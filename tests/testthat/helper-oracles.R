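# Independent oracle implementations, written as direct transcriptions of
# the definitions and kept deliberately naive.  They never call the package
# code paths they are used to check.

# Mean pairwise difference at a site by enumerating every haplotype pair:
# c derived copies among n haplotypes.
oraclePiPairwise <- function(c, n) {
  if (n < 2) return(NA_real_)
  hap <- c(rep(1, c), rep(0, n - c))
  diffs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) diffs <- diffs + (hap[i] != hap[j])
  }
  diffs / choose(n, 2)
}

# Weir & Cockerham (1984) two-population variance components, transcribed
# from the published formulas with heterozygosity at its random-mating
# expectation (scalar arithmetic, no vectorization).
oracleWC84 <- function(c1, n1, c2, n2) {
  r <- 2
  ni <- c(n1 / 2, n2 / 2)                 # diploid sample sizes
  pi_ <- c(c1 / n1, c2 / n2)
  nbar <- mean(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  pbar <- sum(ni * pi_) / sum(ni)
  s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
  hi <- 2 * pi_ * (1 - pi_) * (2 * ni) / (2 * ni - 1)
  hbar <- sum(ni * hi) / sum(ni)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Brute-force ROH caller: explicit window enumeration following the frozen
# rule set, one step at a time.
oracleROH <- function(genotypes, positions, params) {
  n <- length(genotypes)
  w <- params@windowSnp
  het <- !is.na(genotypes) & genotypes == 1
  mis <- is.na(genotypes)
  homWin <- logical(n)
  for (i in seq_len(n)) {
    win <- i:min(i + w - 1, n)
    homWin[i] <- sum(het[win]) <= params@windowHet &&
      sum(mis[win]) <= params@windowMissing
  }
  qualify <- logical(n)
  for (j in seq_len(n)) {
    spans <- max(1, j - w + 1):j
    qualify[j] <- mean(homWin[spans]) >= params@windowThreshold
  }
  segs <- list()
  run <- integer(0)
  flush <- function(run) {
    while (length(run) && (het[run[1]] || mis[run[1]])) run <- run[-1]
    while (length(run) && (het[run[length(run)]] || mis[run[length(run)]]))
      run <- run[-length(run)]
    if (length(run) < params@minSnps) return(NULL)
    lenKb <- (positions[run[length(run)]] - positions[run[1]] + 1) / 1000
    if (lenKb < params@minKb) return(NULL)
    if (lenKb / length(run) > params@densityKb) return(NULL)
    data.frame(start = positions[run[1]],
               end = positions[run[length(run)]],
               n_snps = length(run), length_kb = lenKb)
  }
  for (j in seq_len(n)) {
    if (qualify[j]) {
      if (length(run) &&
          positions[j] - positions[run[length(run)]] > params@gapKb * 1000) {
        segs <- c(segs, list(flush(run)))
        run <- integer(0)
      }
      run <- c(run, j)
    } else if (length(run)) {
      segs <- c(segs, list(flush(run)))
      run <- integer(0)
    }
  }
  if (length(run)) segs <- c(segs, list(flush(run)))
  segs <- segs[!vapply(segs, is.null, TRUE)]
  if (!length(segs)) {
    return(data.frame(start = integer(), end = integer(),
                      n_snps = integer(), length_kb = numeric()))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# Sort-and-slice top-quantile oracle: k-th largest value with ties included.
oracleTopWindows <- function(values, q) {
  ok <- which(!is.na(values))
  k <- max(1, ceiling(q * length(ok)))
  cutoff <- sort(values[ok], decreasing = TRUE)[k]
  ok[values[ok] >= cutoff]
}
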