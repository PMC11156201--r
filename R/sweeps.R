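## Outlier-window detection, two-track intersection, window-to-gene mapping
## and per-clade focal-variant carrier frequencies.

#' Top-quantile outlier windows of a track
#'
#' Order-statistic cutoff: with m non-missing windows, the cutoff is the
#' `ceiling(q * m)`-th largest value and every window with value >= cutoff
#' is returned (ties at the cutoff are all included).
#'
#' @param track window-track data.frame (chrom, start, end, value).
#' @param q upper tail fraction (default 0.05).
#' @return the outlier subset of `track`; attribute `"cutoff"` holds the
#'   threshold used.  A constant track returns every window with a warning.
#' @export
topQuantileWindows <- function(track, q = 0.05) {
  v <- track$value
  ok <- !is.na(v)
  if (!any(ok)) stop("no non-missing window values")
  m <- sum(ok)
  k <- max(1L, ceiling(q * m))
  cutoff <- sort(v[ok], decreasing = TRUE)[k]
  if (max(v[ok]) == min(v[ok])) {
    warning("constant track: all windows tie at the cutoff")
  }
  out <- track[ok & v >= cutoff, , drop = FALSE]
  attr(out, "cutoff") <- cutoff
  out
}

#' Intersect two outlier-window sets and map to genes
#'
#' Both sets must come from the same window grid; a window in one set that
#' overlaps but does not exactly match a window of the other grid is an
#' error naming the first mismatch.  Candidate genes are those whose span
#' overlaps at least one intersected window by >= 1 bp (half-open window
#' coordinates), deduplicated.
#'
#' @param outliersA,outliersB outlier window sets from
#'   [topQuantileWindows()].
#' @param genes data.frame with columns geneId, chrom, start, end (1-based
#'   inclusive gene spans), or a GRanges with a geneId column.
#' @param comparison label stored in the result.
#' @return a CandidateSet list: comparison, windows (intersected),
#'   outliersA/outliersB, genes (character vector of candidate gene ids).
#' @export
intersectAndMap <- function(outliersA, outliersB, genes,
                            comparison = "A-vs-B") {
  keyA <- paste(outliersA$chrom, outliersA$start, outliersA$end)
  keyB <- paste(outliersB$chrom, outliersB$start, outliersB$end)
  ## grid consistency: full-size windows of both sets must share one window
  ## size, and windows sharing a (chrom, start) must agree on the end
  truncA <- outliersA$truncated %||% rep(FALSE, nrow(outliersA))
  truncB <- outliersB$truncated %||% rep(FALSE, nrow(outliersB))
  sizes <- unique(c((outliersA$end - outliersA$start)[!truncA],
                    (outliersB$end - outliersB$start)[!truncB]))
  if (length(sizes) > 1) {
    stop(sprintf("window grids differ: window sizes %s",
                 paste(sizes, collapse = " vs ")))
  }
  sA <- paste(outliersA$chrom, outliersA$start)
  sB <- paste(outliersB$chrom, outliersB$start)
  shared <- intersect(sA, sB)
  mism <- shared[outliersA$end[match(shared, sA)] !=
                   outliersB$end[match(shared, sB)]]
  if (length(mism)) {
    stop("window grids differ: window starting at ", mism[1],
         " has different ends in the two tracks")
  }
  inter <- outliersA[keyA %in% keyB, , drop = FALSE]
  if (methods::is(genes, "GRanges")) {
    genes <- data.frame(geneId = genes$geneId,
                        chrom = as.character(GenomicRanges::seqnames(genes)),
                        start = GenomicRanges::start(genes),
                        end = GenomicRanges::end(genes),
                        stringsAsFactors = FALSE)
  }
  hit <- character(0)
  if (nrow(inter) && nrow(genes)) {
    gw <- GenomicRanges::GRanges(inter$chrom,
                                 IRanges::IRanges(inter$start + 1L,
                                                  inter$end))
    gg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
    ov <- GenomicRanges::findOverlaps(gg, gw)
    hit <- unique(genes$geneId[unique(S4Vectors::queryHits(ov))])
  }
  structure(list(comparison = comparison, windows = inter,
                 outliersA = outliersA, outliersB = outliersB,
                 genes = sort(hit)),
            class = "CandidateSet")
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat(sprintf("CandidateSet '%s': %d + %d outlier windows, %d intersected, %d candidate genes\n",
              x$comparison, nrow(x$outliersA), nrow(x$outliersB),
              nrow(x$windows), length(x$genes)))
  invisible(x)
}

#' Genes shared between two candidate sets (parallel selection candidates)
#'
#' @param setP,setQ CandidateSet objects from [intersectAndMap()] (or plain
#'   character vectors of gene ids).
#' @return sorted character vector of shared gene ids.
#' @export
parallelCandidates <- function(setP, setQ) {
  gp <- if (is.character(setP)) setP else setP$genes
  gq <- if (is.character(setQ)) setQ else setQ$genes
  sort(intersect(gp, gq))
}

#' Per-clade carrier proportion and derived allele frequency at one site
#'
#' @param ds a [GenotypeDataset-class].
#' @param cladeMap data.frame with columns sample, clade.
#' @param chrom,pos the site (must be present in `ds`).
#' @param derivedAllele which allele is derived (must be the site's ref or
#'   alt).
#' @return data.frame per clade: nCalled (individuals), carrierProp
#'   (fraction of called individuals with derived dosage >= 1), daf.
#' @export
carrierFrequency <- function(ds, cladeMap, chrom, pos, derivedAllele) {
  i <- which(ds@chrom == chrom & ds@pos == pos)
  if (!length(i)) stop(sprintf("site %s:%d not in dataset", chrom, pos))
  d <- dosages(ds)[i, ]
  if (derivedAllele == ds@ref[i]) {
    d <- 2L - d
  } else if (derivedAllele != ds@alt[i]) {
    stop("derivedAllele matches neither ref nor alt at the site")
  }
  rows <- lapply(split(cladeMap$sample, cladeMap$clade), function(smp) {
    v <- d[smp]
    called <- !is.na(v)
    data.frame(nCalled = sum(called),
               carrierProp = if (any(called)) mean(v[called] >= 1L) else NA_real_,
               daf = if (any(called)) sum(v[called]) / (2 * sum(called))
                     else NA_real_)
  })
  res <- cbind(data.frame(clade = names(rows), stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(res) <- NULL
  res
}
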