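## Scanning-window runs-of-homozygosity detection (PLINK --homozyg style).
##
## Frozen algorithm, shared with the brute-force oracle used in the tests:
##  1. windows of `windowSnp` SNPs slide one SNP at a time; windows reaching
##     past the last SNP are truncated and still count;
##  2. a window is homozygous iff it has <= windowHet heterozygous and
##     <= windowMissing missing calls;
##  3. a SNP qualifies iff the fraction of homozygous windows among the
##     windows containing it is >= windowThreshold;
##  4. maximal runs of consecutive qualifying SNPs are split wherever the
##     gap between adjacent SNPs exceeds gapKb;
##  5. run boundaries are trimmed of heterozygous/missing SNPs;
##  6. surviving runs must have >= minSnps SNPs, span >= minKb kb
##     (end - start + 1 bp), and satisfy the density bound
##     length_kb / n_snps <= densityKb.

#' Detect runs of homozygosity in one sample on one chromosome
#'
#' @param genotypes dosage vector (0 = hom ref, 1 = het, 2 = hom alt,
#'   NA = missing), ordered along the chromosome.
#' @param positions sorted 1-based bp positions (unsorted input is an
#'   error).
#' @param params a [ROHParams-class] (defaults: [rohParams()]).
#' @return data.frame of segments: start, end, n_snps, length_kb.
#' @export
detectROH <- function(genotypes, positions, params = rohParams()) {
  n <- length(genotypes)
  stopifnot(length(positions) == n)
  if (n > 1 && any(diff(positions) < 0)) stop("positions must be sorted")
  empty <- data.frame(start = integer(), end = integer(),
                      n_snps = integer(), length_kb = numeric())
  if (n == 0) return(empty)
  w <- as.integer(params@windowSnp)
  het <- !is.na(genotypes) & genotypes == 1L
  mis <- is.na(genotypes)
  cumHet <- c(0L, cumsum(het))
  cumMis <- c(0L, cumsum(mis))
  ends <- pmin(seq_len(n) + w - 1L, n)
  hetC <- cumHet[ends + 1L] - cumHet[seq_len(n)]
  misC <- cumMis[ends + 1L] - cumMis[seq_len(n)]
  homWin <- hetC <= params@windowHet & misC <= params@windowMissing
  cumHom <- c(0L, cumsum(homWin))
  j <- seq_len(n)
  lo <- pmax(1L, j - w + 1L)
  hits <- cumHom[j + 1L] - cumHom[lo]
  denom <- j - lo + 1L
  qualify <- hits / denom >= params@windowThreshold

  q <- which(qualify)
  if (!length(q)) return(empty)
  gapBp <- params@gapKb * 1000
  newRun <- c(TRUE, diff(q) > 1L |
                (positions[q[-1]] - positions[q[-length(q)]]) > gapBp)
  grp <- cumsum(newRun)
  segs <- lapply(split(q, grp), function(run) {
    while (length(run) && (het[run[1]] || mis[run[1]])) run <- run[-1]
    while (length(run) && (het[run[length(run)]] || mis[run[length(run)]]))
      run <- run[-length(run)]
    if (length(run) < params@minSnps) return(NULL)
    lenKb <- (positions[run[length(run)]] - positions[run[1]] + 1) / 1000
    if (lenKb < params@minKb) return(NULL)
    if (lenKb / length(run) > params@densityKb) return(NULL)
    data.frame(start = positions[run[1]], end = positions[run[length(run)]],
               n_snps = length(run), length_kb = lenKb)
  })
  segs <- segs[!vapply(segs, is.null, TRUE)]
  if (!length(segs)) return(empty)
  res <- do.call(rbind, segs)
  rownames(res) <- NULL
  res
}

#' Detect ROH for every sample and chromosome of a dataset
#'
#' @param ds a [GenotypeDataset-class].
#' @param params a [ROHParams-class].
#' @return data.frame of segments: sample, chrom, start, end, n_snps,
#'   length_kb.
#' @export
rohScan <- function(ds, params = rohParams()) {
  out <- list()
  d <- dosages(ds)
  for (ch in unique(ds@chrom)) {
    i <- which(ds@chrom == ch)
    for (s in sampleIds(ds)) {
      segs <- detectROH(d[i, s], ds@pos[i], params)
      if (nrow(segs)) {
        out[[length(out) + 1L]] <-
          cbind(data.frame(sample = s, chrom = ch,
                           stringsAsFactors = FALSE), segs)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_snps = integer(), length_kb = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize ROH per clade
#'
#' @param segments output of [rohScan()] (or [detectROH()] with sample and
#'   chrom columns added).
#' @param cladeMap data.frame with columns sample, clade.
#' @param genomeLengthBp assayed genome length for F_ROH (sum of per-sample
#'   ROH length over this length).
#' @return data.frame per clade: nSegments, totalKb (summed over the
#'   clade's samples), meanSegKb, meanTotalKbPerSample, meanFroh.
#'   Per-sample totals are attached as the `"samples"` attribute.
#' @export
rohSummary <- function(segments, cladeMap, genomeLengthBp) {
  unknown <- setdiff(unique(segments$sample), cladeMap$sample)
  if (length(unknown)) {
    warning("segments for samples absent from the clade map dropped: ",
            paste(unknown, collapse = ", "))
    segments <- segments[segments$sample %in% cladeMap$sample, , drop = FALSE]
  }
  perSample <- data.frame(sample = cladeMap$sample,
                          clade = cladeMap$clade,
                          totalKb = 0, nSegments = 0L,
                          stringsAsFactors = FALSE)
  if (nrow(segments)) {
    tot <- tapply(segments$length_kb, segments$sample, sum)
    cnt <- tapply(segments$length_kb, segments$sample, length)
    m <- match(names(tot), perSample$sample)
    perSample$totalKb[m] <- tot
    perSample$nSegments[m] <- cnt
  }
  perSample$froh <- perSample$totalKb * 1000 / genomeLengthBp
  agg <- lapply(split(perSample, perSample$clade), function(x) {
    data.frame(clade = x$clade[1],
               nSegments = sum(x$nSegments),
               totalKb = sum(x$totalKb),
               meanSegKb = if (sum(x$nSegments) > 0)
                 sum(x$totalKb) / sum(x$nSegments) else 0,
               meanTotalKbPerSample = mean(x$totalKb),
               meanFroh = mean(x$froh),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, agg)
  rownames(res) <- NULL
  attr(res, "samples") <- perSample
  res
}
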