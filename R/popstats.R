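## Per-site and windowed nucleotide diversity, Weir-Cockerham FST, and
## class-stratified unfolded site-frequency spectra.

#' Per-site nucleotide diversity
#'
#' Mean pairwise difference at a biallelic site with `c` copies of one
#' allele among `n` called haploid genomes: `2 c (n - c) / (n (n - 1))`.
#'
#' @param c allele copy count (vectorized).
#' @param n called haploid genomes (vectorized).
#' @return per-site pi; NA where `n < 2`.
#' @export
sitePi <- function(c, n) {
  stopifnot(all(c >= 0 & c <= n))
  ifelse(n >= 2, 2 * c * (n - c) / (n * (n - 1)), NA_real_)
}

#' Windowed nucleotide diversity
#'
#' Window value = sum of per-SNP [sitePi()] over the SNPs in the window,
#' divided by the full window length in bp (monomorphic positions contribute
#' zero), the convention behind per-bp pi values like 1e-3.  Supports the
#' 50 kb / 10 kb sliding mode and the nonoverlapping 10 kb mode used for
#' four-fold degenerate-site diversity (pi_s) when `sites` restricts the
#' SNP set.
#'
#' @param ds a [GenotypeDataset-class].
#' @param samples optional sample subset defining the group.
#' @param windowBp,stepBp window geometry (half-open `[start, end)` bp);
#'   equal values give nonoverlapping windows.
#' @param chromLengths named vector of chromosome lengths; inferred from the
#'   maximum SNP position when omitted.
#' @param sites optional data.frame (chrom, pos) restricting the SNPs used
#'   (e.g. a four-fold degenerate site list).
#' @param minSnps windows with fewer SNPs get NA (default 0: empty windows
#'   report 0, the definitional value).
#' @return window track data.frame: chrom, start, end, n_snps, value,
#'   statistic, plus a `truncated` flag for windows clipped at a chromosome
#'   end.
#' @export
windowedPi <- function(ds, samples = NULL, windowBp = 50000L,
                       stepBp = 10000L, chromLengths = NULL, sites = NULL,
                       minSnps = 0L) {
  if (nSites(ds) == 0) stop("empty dataset")
  keep <- seq_len(nSites(ds))
  if (!is.null(sites)) {
    keep <- which(siteKey(ds@chrom, ds@pos) %in% siteKey(sites$chrom,
                                                         sites$pos))
  }
  ac <- alleleCounts(ds[keep, ], samples)
  pp <- sitePi(ac$c, ac$n)
  pp[is.na(pp)] <- 0
  perWindowTrack(ds@chrom[keep], ds@pos[keep], pp, chromLengths, windowBp,
                 stepBp, statistic = "pi", minSnps = minSnps)
}

## Shared window machinery: lays the (windowBp, stepBp) grid per chromosome
## and aggregates per-site values.  `values` may be a matrix (sites x k)
## whose columns are summed per window before `combine` maps the column
## sums to the window value.
perWindowTrack <- function(chrom, pos, values, chromLengths, windowBp,
                           stepBp, statistic, minSnps = 0L,
                           combine = NULL, perBp = TRUE) {
  values <- as.matrix(values)
  chroms <- if (!is.null(chromLengths)) names(chromLengths) else
    sort(unique(chrom))
  out <- list()
  for (ch in chroms) {
    L <- if (!is.null(chromLengths)) chromLengths[[ch]] else {
      m <- max(pos[chrom == ch], 0L)
      max(m, windowBp)
    }
    grid <- windowGrid(L, windowBp, stepBp)
    if (any(grid$truncated)) {
      warning(sprintf("chromosome %s shorter than one window; truncated", ch))
    }
    i <- which(chrom == ch)
    val <- numeric(nrow(grid)); nsnp <- integer(nrow(grid))
    for (w in seq_len(nrow(grid))) {
      ## half-open [start, end) on 0-based window bounds, 1-based positions
      inw <- i[pos[i] > grid$start[w] & pos[i] <= grid$end[w]]
      nsnp[w] <- length(inw)
      if (length(inw) < minSnps) { val[w] <- NA_real_; next }
      cs <- colSums(values[inw, , drop = FALSE])
      val[w] <- if (!is.null(combine)) combine(cs) else
        cs[1] / if (perBp) (grid$end[w] - grid$start[w]) else 1
    }
    out[[ch]] <- data.frame(chrom = ch, start = grid$start, end = grid$end,
                            n_snps = nsnp, value = val,
                            statistic = statistic,
                            truncated = grid$truncated,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Weir-Cockerham variance components at one biallelic site
#'
#' The two-population diploid random-mating estimator on allele counts
#' (no inbreeding correction): heterozygosity enters at its Hardy-Weinberg
#' expectation `2 p q * 2n/(2n - 1)`.  Site FST is `a / (a + b + c)`; the
#' estimator may legitimately go negative.
#'
#' @param c1,n1 allele copy count and called haploid genomes in population 1.
#' @param c2,n2 same for population 2.
#' @return named vector (or 3-column matrix when vectorized) of the a, b, c
#'   components.
#' @export
wcFstSite <- function(c1, n1, c2, n2) {
  if (any(n1 < 2 | n2 < 2)) stop("need at least one diploid (n >= 2) per population")
  ## diploid sample sizes and allele frequencies
  nd1 <- n1 / 2; nd2 <- n2 / 2
  p1 <- c1 / n1; p2 <- c2 / n2
  r <- 2
  nbar <- (nd1 + nd2) / r
  nc <- (r * nbar - (nd1^2 + nd2^2) / (r * nbar)) / (r - 1)
  pbar <- (nd1 * p1 + nd2 * p2) / (r * nbar)
  s2 <- (nd1 * (p1 - pbar)^2 + nd2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  h1 <- 2 * p1 * (1 - p1) * n1 / (n1 - 1)
  h2 <- 2 * p2 * (1 - p2) * n2 / (n2 - 1)
  hbar <- (nd1 * h1 + nd2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (length(c1) == 1) c(a = a, b = b, c = cc) else cbind(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham FST between two groups
#'
#' Ratio-of-sums ("weighted") estimator per window:
#' `sum(a) / sum(a + b + c)` over the window's sites.  Negative window
#' values are retained; windows with fewer than `minSnps` informative sites,
#' or a zero denominator, are NA.
#'
#' @param ds a [GenotypeDataset-class].
#' @param groupA,groupB sample id vectors (each with >= 1 diploid called per
#'   site; sites failing that in either group are skipped).
#' @param windowBp,stepBp,chromLengths window geometry as in [windowedPi()].
#' @param minSnps minimum informative SNPs per window (default 10).
#' @return window track data.frame (chrom, start, end, n_snps, value).
#' @export
windowedFst <- function(ds, groupA, groupB, windowBp = 50000L,
                        stepBp = 10000L, chromLengths = NULL,
                        minSnps = 10L) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  acA <- alleleCounts(ds, groupA)
  acB <- alleleCounts(ds, groupB)
  use <- acA$n >= 2 & acB$n >= 2
  comp <- matrix(0, nSites(ds), 2)  # columns: a, a+b+c
  if (any(use)) {
    w <- wcFstSite(acA$c[use], acA$n[use], acB$c[use], acB$n[use])
    w <- matrix(w, ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
    comp[use, 1] <- w[, "a"]
    comp[use, 2] <- w[, "a"] + w[, "b"] + w[, "c"]
  }
  tr <- perWindowTrack(ds@chrom[use], ds@pos[use],
                       comp[use, , drop = FALSE], chromLengths, windowBp,
                       stepBp, statistic = "fst", minSnps = minSnps,
                       combine = function(cs)
                         if (cs[2] == 0) NA_real_ else cs[1] / cs[2])
  tr
}

#' Unfolded site-frequency spectrum with hypergeometric projection
#'
#' Each site's (derived, called) haplotype counts are projected to a fixed
#' sample of `projectionN` haplotypes: site j adds
#' `P(i derived | K_j, N_j, projectionN)` to bin i (expected counts, the
#' standard projection).  Mass projected to the fixed classes 0 and
#' `projectionN` is excluded.  Sites polarized as resolved_external have no
#' single derived allele and must not be passed in.
#'
#' @param derived per-site derived allele counts.
#' @param called per-site called haploid genomes.
#' @param projectionN target haplotype sample size.
#' @param siteClass,group labels attached to the result.
#' @return data.frame with columns derivedCount (1 .. projectionN-1) and
#'   nSites (expected counts); attributes projectionN, siteClass, group,
#'   nProjectable.
#' @export
computeSFS <- function(derived, called, projectionN, siteClass = NA,
                       group = NA) {
  stopifnot(length(derived) == length(called), projectionN >= 2)
  ok <- !is.na(derived) & !is.na(called) & called >= projectionN
  if (length(derived) > 0 && mean(!ok) > 0.5) {
    stop("projectionN exceeds the called haplotypes at more than half of ",
         "the sites; choose a smaller projection")
  }
  K <- derived[ok]; N <- called[ok]
  xi <- numeric(projectionN - 1)
  for (i in seq_len(projectionN - 1)) {
    xi[i] <- sum(dhyper(i, K, N - K, projectionN))
  }
  structure(data.frame(derivedCount = seq_len(projectionN - 1), nSites = xi),
            projectionN = projectionN, siteClass = siteClass, group = group,
            nProjectable = sum(ok))
}
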