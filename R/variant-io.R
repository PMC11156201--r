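#' Read a VCF into a GenotypeDataset
#'
#' Parses GT (and DP when present) fields via \pkg{vcfR}.  Multi-allelic and
#' non-SNP records are dropped; the exclusion counts are attached as the
#' `"excluded"` attribute and reported via `message()`.  Coordinates are
#' 1-based, as in the VCF itself.
#'
#' @param path path to an (uncompressed or gzipped) VCF with a GT FORMAT
#'   field.
#' @return a [GenotypeDataset-class]; attribute `"excluded"` holds the
#'   counts of dropped multi-allelic and non-SNP records.
#' @export
readVCF <- function(path) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0) {
    ds <- GenotypeDataset(
      matrix(integer(0), 0, 0, dimnames = list(NULL, character(0))),
      chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0))
    attr(ds, "excluded") <- c(multiallelic = 0L, nonSNP = 0L)
    return(ds)
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  isSnp <- !multi & ref %in% BASES & alt %in% BASES
  excluded <- c(multiallelic = sum(multi), nonSNP = sum(!multi & !isSnp))
  if (any(!isSnp)) {
    message(sprintf("readVCF: dropped %d multi-allelic and %d non-SNP records",
                    excluded[["multiallelic"]], excluded[["nonSNP"]]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[isSnp, , drop = FALSE]
  alleles <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow(alleles), ncol(alleles),
                   dimnames = list(NULL, colnames(alleles)))
  dosage[alleles == "0/0"] <- 0L
  dosage[alleles %in% c("0/1", "1/0")] <- 1L
  dosage[alleles == "1/1"] <- 2L
  depth <- NULL
  if ("DP" %in% unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))) {
    depth <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    depth <- depth[isSnp, , drop = FALSE]
    rownames(depth) <- NULL
  }
  ds <- GenotypeDataset(dosage,
                        chrom = fix[isSnp, "CHROM"],
                        pos = as.integer(fix[isSnp, "POS"]),
                        ref = ref[isSnp], alt = alt[isSnp], depth = depth)
  attr(ds, "excluded") <- excluded
  ds
}

#' Write a GenotypeDataset to a minimal VCF 4.2 (GT only)
#'
#' @param ds a [GenotypeDataset-class].
#' @param path output path.
#' @param contigs optional named vector of contig lengths for the header.
#' @return the path, invisibly.
#' @export
writeVCF <- function(ds, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=purgescan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  if (!is.null(contigs)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sampleIds(ds)), collapse = "\t"), con)
  n <- nSites(ds)
  if (n > 0) {
    gtChar <- matrix("./.", n, nSamples(ds))
    d <- dosages(ds)
    gtChar[!is.na(d) & d == 0L] <- "0/0"
    gtChar[!is.na(d) & d == 1L] <- "0/1"
    gtChar[!is.na(d) & d == 2L] <- "1/1"
    lines <- paste(ds@chrom, ds@pos, ".", ds@ref, ds@alt, ".", ".", ".", "GT",
                   sep = "\t")
    lines <- paste(lines, apply(gtChar, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Filter variants on depth, missingness and minor allele frequency
#'
#' Mirrors the common resequencing filter (vcftools semantics): calls with
#' depth below `minDepth` are first set missing (skipped with a warning when
#' the dataset carries no depth information), then sites with a called
#' fraction below `minCalled` (vcftools `--max-missing`) or a minor allele
#' frequency below `minMaf` (computed over called alleles only) are removed.
#'
#' @param ds a [GenotypeDataset-class].
#' @param minCalled minimum fraction of called genotypes per site (0.8
#'   reproduces `--max-missing 0.8`).
#' @param minMaf minimum minor allele frequency (`--maf`).
#' @param minDepth minimum per-call depth (`--minDP`); 0 disables.
#' @return list with `dataset` (the filtered [GenotypeDataset-class]) and
#'   `counts`, the per-rule removal counts (low-depth calls masked, sites
#'   dropped for missingness, sites dropped for MAF).
#' @export
filterVariants <- function(ds, minCalled = 0.8, minMaf = 0.05, minDepth = 3) {
  stopifnot(minCalled >= 0, minCalled <= 1, minMaf >= 0, minMaf <= 0.5)
  d <- dosages(ds)
  lowDepthCalls <- 0L
  if (minDepth > 0) {
    if (is.null(callDepth(ds))) {
      warning("no depth information; depth filter skipped")
    } else {
      mask <- !is.na(d) & (is.na(callDepth(ds)) | callDepth(ds) < minDepth)
      lowDepthCalls <- sum(mask)
      d[mask] <- NA_integer_
    }
  }
  called <- rowMeans(!is.na(d))
  keepCalled <- called >= minCalled
  cnt <- rowSums(d, na.rm = TRUE)
  nAll <- 2 * rowSums(!is.na(d))
  maf <- ifelse(nAll > 0, pmin(cnt, nAll - cnt) / nAll, 0)
  keepMaf <- maf >= minMaf
  keep <- keepCalled & keepMaf
  counts <- c(lowDepthCalls = lowDepthCalls,
              missingness = sum(!keepCalled),
              maf = sum(keepCalled & !keepMaf))
  out <- new("GenotypeDataset",
             dosage = d[keep, , drop = FALSE],
             chrom = ds@chrom[keep], pos = ds@pos[keep],
             ref = ds@ref[keep], alt = ds@alt[keep],
             depth = if (is.null(ds@depth)) NULL
                     else ds@depth[keep, , drop = FALSE])
  list(dataset = out, counts = counts)
}

#' Read a per-window score track (e.g. an XP-CLR output)
#'
#' @param path TSV with header columns chrom, start, end, score
#'   (half-open `[start, end)` coordinates).
#' @return a sorted window-track data.frame (chrom, start, end, value);
#'   non-numeric scores become `NA` and are excluded from quantiles
#'   downstream.  Duplicated (chrom, start, end) windows are an error.
#' @export
readWindowScores <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c("character", "integer", "integer",
                                 "character"))
  names(x)[1:4] <- c("chrom", "start", "end", "value")
  x$value <- suppressWarnings(as.numeric(x$value))
  key <- paste(x$chrom, x$start, x$end)
  if (anyDuplicated(key)) {
    stop("duplicated windows in score track: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read a sample-to-clade map
#'
#' @param path TSV with header columns sample, clade, altitude
#'   (altitude in \{"high", "low"\}).
#' @return validated data.frame.
#' @export
readCladeMap <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "clade", "altitude") %in% names(x)))
  if (anyDuplicated(x$sample)) stop("samples assigned to more than one clade")
  if (!all(x$altitude %in% c("high", "low")))
    stop("altitude must be 'high' or 'low'")
  x
}

#' Read a per-site outgroup-allele table
#'
#' @param path TSV with header columns chrom, pos, og1, og2 (single-base
#'   alleles or "." / NA for missing).
#' @return data.frame with NA for missing alleles; duplicate (chrom, pos)
#'   rows are an error.
#' @export
readOutgroupTable <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = c("NA", "."))
  stopifnot(all(c("chrom", "pos", "og1", "og2") %in% names(x)))
  if (anyDuplicated(siteKey(x$chrom, x$pos)))
    stop("duplicate (chrom, pos) rows in outgroup table")
  x
}

#' Read a site list (e.g. a dnSNP list)
#'
#' @param path TSV with header columns chrom, pos.
#' @return data.frame of unique sites.
#' @export
readSiteList <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos") %in% names(x)))
  unique(x[, c("chrom", "pos")])
}
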