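#' @rdname GenotypeDataset
#' @param x a `GenotypeDataset`.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname GenotypeDataset
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeDataset
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeDataset
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeDataset
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname GenotypeDataset
#' @export
setGeneric("callDepth", function(x) standardGeneric("callDepth"))

#' @rdname GenotypeDataset
#' @export
setMethod("nSites", "GenotypeDataset", function(x) nrow(x@dosage))

#' @rdname GenotypeDataset
#' @export
setMethod("nSamples", "GenotypeDataset", function(x) ncol(x@dosage))

#' @rdname GenotypeDataset
#' @export
setMethod("sampleIds", "GenotypeDataset", function(x) colnames(x@dosage))

#' @rdname GenotypeDataset
#' @export
setMethod("dosages", "GenotypeDataset", function(x) x@dosage)

#' @rdname GenotypeDataset
#' @export
setMethod("siteInfo", "GenotypeDataset", function(x) {
  data.frame(chrom = x@chrom, pos = x@pos, ref = x@ref, alt = x@alt,
             stringsAsFactors = FALSE)
})

#' @rdname GenotypeDataset
#' @export
setMethod("callDepth", "GenotypeDataset", function(x) x@depth)

#' Subset a GenotypeDataset by sites (i) and/or samples (j)
#'
#' @param x a `GenotypeDataset`.
#' @param i site indices (integer/logical).
#' @param j sample indices or ids.
#' @param ... ignored.
#' @param drop ignored; always returns a `GenotypeDataset`.
#' @export
setMethod("[", "GenotypeDataset", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSites(x))
  if (missing(j)) j <- seq_len(nSamples(x))
  new("GenotypeDataset",
      dosage = x@dosage[i, j, drop = FALSE],
      chrom = x@chrom[i], pos = x@pos[i], ref = x@ref[i], alt = x@alt[i],
      depth = if (is.null(x@depth)) NULL else x@depth[i, j, drop = FALSE])
})

setMethod("show", "GenotypeDataset", function(object) {
  cat("GenotypeDataset:", nSites(object), "biallelic sites x",
      nSamples(object), "samples\n")
  if (nSites(object) > 0) {
    tab <- table(object@chrom)
    cat("  chromosomes:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
    miss <- mean(is.na(object@dosage))
    cat(sprintf("  missing calls: %.2f%%; depth: %s\n", 100 * miss,
                if (is.null(object@depth)) "absent" else "present"))
  }
})

## Alt-allele count and called-allele count per site, over a sample subset.
## Returns a list(c = alt copies, n = called haploid genomes) per site.
alleleCounts <- function(ds, samples = NULL) {
  d <- ds@dosage
  if (!is.null(samples)) d <- d[, samples, drop = FALSE]
  called <- !is.na(d)
  list(c = rowSums(d, na.rm = TRUE), n = 2L * rowSums(called))
}
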