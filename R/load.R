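## Per-sample genetic-load proxy and clade summaries.
##
## The proxy is the ratio of a sample's derived deleterious-missense (dnSNP)
## allele dosage to its derived four-fold-degenerate allele dosage: the
## neutral denominator controls for how much derived variation the sample
## carries overall, so the ratio tracks the deleterious fraction of the
## genome rather than raw diversity.

#' Per-sample genetic load proxy
#'
#' "Derived allele counts" are diploid dosages (a heterozygote contributes
#' 1, a derived homozygote 2), summed over called genotypes only.  Sites
#' polarized against both focal alleles (resolved_external) add a constant
#' dosage of 2 to every sample and are excluded by default.
#'
#' @param derivedDosage sites x samples derived-allele dosage matrix from
#'   [polarizeDataset()] (NA = missing call or unresolved site).
#' @param siteKeys per-row site keys (`chrom:pos`), used to pick out the two
#'   site classes.
#' @param dnsnpSites,fourfoldSites data.frames (chrom, pos) of the
#'   deleterious and four-fold degenerate site lists; they must be disjoint.
#' @param status optional per-row polarization status; used to drop
#'   resolved_external rows unless `includeExternal`.
#' @param includeExternal keep resolved_external sites (constant offset).
#' @param carriers count carriers (dosage >= 1 contributes 1) instead of
#'   dosages.
#' @return data.frame per sample: derived dnSNP and four-fold allele sums,
#'   callable-site counts per class, and `load` (NA, flagged via the
#'   `undefined` column, when the denominator is 0).
#' @export
loadTable <- function(derivedDosage, siteKeys, dnsnpSites, fourfoldSites,
                      status = NULL, includeExternal = FALSE,
                      carriers = FALSE) {
  dnKey <- siteKey(dnsnpSites$chrom, dnsnpSites$pos)
  ffKey <- siteKey(fourfoldSites$chrom, fourfoldSites$pos)
  if (length(intersect(dnKey, ffKey)))
    stop("dnSNP and four-fold site lists must be disjoint")
  keep <- rep(TRUE, length(siteKeys))
  if (!is.null(status) && !includeExternal) keep <- status != "resolved_external"
  d <- derivedDosage
  if (carriers) d <- (d >= 1L) + 0L
  dn <- d[keep & siteKeys %in% dnKey, , drop = FALSE]
  ff <- d[keep & siteKeys %in% ffKey, , drop = FALSE]
  num <- colSums(dn, na.rm = TRUE)
  den <- colSums(ff, na.rm = TRUE)
  res <- data.frame(sample = colnames(derivedDosage),
                    dnsnpAlleles = num, fourfoldAlleles = den,
                    dnsnpCalled = colSums(!is.na(dn)),
                    fourfoldCalled = colSums(!is.na(ff)),
                    load = ifelse(den > 0, num / den, NA_real_),
                    undefined = den == 0,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Load proxy for a single sample
#'
#' @inheritParams loadTable
#' @param sample sample id.
#' @return one-row data.frame, see [loadTable()].
#' @export
sampleLoad <- function(derivedDosage, siteKeys, dnsnpSites, fourfoldSites,
                       sample, ...) {
  tab <- loadTable(derivedDosage[, sample, drop = FALSE], siteKeys,
                   dnsnpSites, fourfoldSites, ...)
  tab
}

#' Per-clade load summary with pairwise rank tests
#'
#' Undefined loads are excluded everywhere; clades of size 1 keep their
#' median but are excluded from the Wilcoxon rank-sum tests.  Pairwise
#' p-values are Benjamini-Hochberg adjusted across the pairs.
#'
#' @param reports output of [loadTable()].
#' @param cladeMap data.frame with columns sample, clade.
#' @return list with `clades` (median, IQR, n per clade) and `tests`
#'   (cladeA, cladeB, p, padj).
#' @export
cladeLoadTable <- function(reports, cladeMap) {
  x <- merge(reports[!reports$undefined & !is.na(reports$load), ],
             cladeMap[, c("sample", "clade")], by = "sample")
  if (length(unique(x$clade)) < 2) stop("need at least two clades")
  cl <- split(x$load, x$clade)
  clades <- data.frame(
    clade = names(cl),
    n = vapply(cl, length, 0L),
    median = vapply(cl, median, 0),
    iqr = vapply(cl, function(v) diff(quantile(v, c(0.25, 0.75))), 0),
    stringsAsFactors = FALSE)
  rownames(clades) <- NULL
  testable <- names(cl)[vapply(cl, length, 0L) >= 2]
  pairs <- if (length(testable) >= 2) t(combn(testable, 2)) else
    matrix(character(0), 0, 2)
  tests <- data.frame(cladeA = pairs[, 1], cladeB = pairs[, 2],
                      p = rep(NA_real_, nrow(pairs)),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    tests$p[i] <- suppressWarnings(
      wilcox.test(cl[[pairs[i, 1]]], cl[[pairs[i, 2]]], exact = FALSE)$p.value)
  }
  tests$padj <- p.adjust(tests$p, method = "BH")
  list(clades = clades, tests = tests)
}

#' Relationship between neutral diversity (pi_s) and load across clades
#'
#' @param cladePis named vector of per-clade median four-fold diversity.
#' @param cladeLoads named vector of per-clade median load (same clades).
#' @return data.frame with Pearson and Spearman coefficients and the fitted
#'   least-squares slope of load on pi_s; coefficients are NA (flagged) for
#'   constant input.  No causal claim is encoded.
#' @export
pisLoadRelation <- function(cladePis, cladeLoads) {
  stopifnot(length(cladePis) >= 3)
  common <- intersect(names(cladePis), names(cladeLoads))
  x <- cladePis[common]; y <- cladeLoads[common]
  degenerate <- sd(x) == 0 || sd(y) == 0
  if (degenerate) warning("constant input; correlation undefined")
  data.frame(
    n = length(common),
    pearson = if (degenerate) NA_real_ else cor(x, y, method = "pearson"),
    spearman = if (degenerate) NA_real_ else cor(x, y, method = "spearman"),
    slope = if (degenerate) NA_real_ else unname(coef(lm(y ~ x))[2]),
    degenerate = degenerate)
}

#' Fraction of segregating sites with derived allele frequency below a
#' threshold
#'
#' @param sfs a spectrum from [computeSFS()].
#' @param dafThreshold frequency threshold (default 0.1; strict inequality
#'   `i/n < t`).
#' @return proportion in `[0, 1]`; NA (with a warning) for an empty
#'   spectrum.
#' @export
rareFraction <- function(sfs, dafThreshold = 0.1) {
  n <- attr(sfs, "projectionN")
  tot <- sum(sfs$nSites)
  if (tot == 0) {
    warning("empty spectrum; rare fraction undefined")
    return(NA_real_)
  }
  sum(sfs$nSites[sfs$derivedCount / n < dafThreshold]) / tot
}
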