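## Codon-aware functional site classification from FASTA + GFF3 CDS models.
## Reimplements the variant-categorization step of resequencing pipelines:
## region classes (CDS / intron / upstream / downstream / intergenic),
## per-site codon degeneracy, and per-variant effects (synonymous /
## nonsynonymous / stopgain / stoploss) with most-severe resolution across
## overlapping transcripts.

EFFECT_SEVERITY <- c(stopgain = 4, stoploss = 3, nonsynonymous = 2,
                     synonymous = 1, noncoding = 0)

## degeneracy of (codon, position): number of the 4 bases at that position
## encoding the same amino acid (4 = four-fold degenerate site)
degeneracyTable <- function() {
  if (!is.null(.purgescan_cache$degTab)) return(.purgescan_cache$degTab)
  gc <- codonTable()
  codons <- names(gc)
  deg <- matrix(NA_integer_, length(codons), 3, dimnames = list(codons, NULL))
  for (cod in codons) {
    for (w in 1:3) {
      aas <- vapply(BASES, function(b) {
        nc <- cod
        substr(nc, w, w) <- b
        gc[[nc]]
      }, "")
      deg[cod, w] <- sum(aas == gc[[cod]])
    }
  }
  .purgescan_cache$degTab <- deg
  deg
}

#' Load a reference genome with its gene models
#'
#' Reads the FASTA and GFF3 (gene/mRNA/CDS features; the phase column is
#' honored) and precomputes, for every coding genomic position, its
#' transcript, codon, position-in-codon and degeneracy.  Transcripts whose
#' CDS length after phase trimming is not divisible by 3 are excluded from
#' codon-based classes with a warning.
#'
#' @param fastaPath reference FASTA.
#' @param gffPath GFF3 with gene, mRNA and CDS features (CDS `Parent`
#'   pointing at the mRNA).
#' @param flankBp distance defining upstream/downstream regions (default
#'   1 kb).
#' @return a `GenomeAnnotation` list used by [classifySite()],
#'   [classifyVariant()] and [fourfoldSites()].
#' @export
loadAnnotation <- function(fastaPath, gffPath, flankBp = 1000L) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chromChars <- lapply(seq_along(seqs), function(i)
    strsplit(as.character(seqs[[i]]), "")[[1]])
  names(chromChars) <- names(seqs)
  gr <- rtracklayer::import(gffPath)
  grType <- as.character(gr$type)
  mrna <- gr[grType == "mRNA"]
  ## plain table of CDS segments: S4 subsetting per transcript is too slow
  cdsF <- gr[grType == "CDS"]
  cdsTab <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(cdsF)),
    start = GenomicRanges::start(cdsF), end = GenomicRanges::end(cdsF),
    strand = as.character(GenomicRanges::strand(cdsF)),
    phase = if (!is.null(cdsF$phase)) cdsF$phase else
      rep(NA_integer_, length(cdsF)),
    parent = vapply(cdsF$Parent, function(p)
      if (length(p)) p[[1]] else NA_character_, ""),
    stringsAsFactors = FALSE)
  gc <- codonTable()
  degTab <- degeneracyTable()

  txIds <- mrna$ID
  txParent <- vapply(mrna$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  cdsByTx <- split(seq_len(nrow(cdsTab)), cdsTab$parent)

  idxRows <- vector("list", length(txIds))
  spanRows <- vector("list", length(txIds))
  for (t in seq_along(txIds)) {
    tid <- txIds[t]
    segs <- cdsTab[cdsByTx[[tid]], , drop = FALSE]
    if (nrow(segs) == 0) next
    ch <- segs$chrom[1]
    strand <- segs$strand[1]
    segs <- segs[order(segs$start, decreasing = (strand == "-")), ,
                 drop = FALSE]  # translation order
    gpos <- unlist(lapply(seq_len(nrow(segs)), function(i) {
      if (strand == "+") seq.int(segs$start[i], segs$end[i])
      else seq.int(segs$end[i], segs$start[i])
    }))
    phase1 <- segs$phase[1]
    if (is.na(phase1)) phase1 <- 0L
    if (phase1 > 0) gpos <- gpos[-seq_len(phase1)]
    if (length(gpos) %% 3L != 0L) {
      warning(sprintf(
        "transcript %s: CDS length not divisible by 3 after phase; excluded from codon classes",
        tid))
      spanRows[[t]] <- data.frame(
        txId = tid, geneId = txParent[t], chrom = ch,
        start = min(segs$start), end = max(segs$end), strand = strand,
        stringsAsFactors = FALSE)
      next
    }
    txBase <- chromChars[[ch]][gpos]
    if (strand == "-") txBase <- chartr("ACGT", "TGCA", txBase)
    nCod <- length(gpos) %/% 3L
    codons <- paste0(txBase[3L * (seq_len(nCod) - 1L) + 1L],
                     txBase[3L * (seq_len(nCod) - 1L) + 2L],
                     txBase[3L * (seq_len(nCod) - 1L) + 3L])
    cpos <- seq_along(gpos)
    within <- (cpos - 1L) %% 3L + 1L
    codAt <- codons[(cpos - 1L) %/% 3L + 1L]
    idxRows[[t]] <- data.frame(
      chrom = ch, gpos = gpos, txId = tid, geneId = txParent[t],
      strand = strand, codon = codAt, within = within,
      deg = degTab[cbind(match(codAt, rownames(degTab)), within)],
      stringsAsFactors = FALSE)
    spanRows[[t]] <- data.frame(
      txId = tid, geneId = txParent[t], chrom = ch,
      start = min(segs$start), end = max(segs$end), strand = strand,
      stringsAsFactors = FALSE)
  }
  ## transcript spans: prefer the mRNA feature's own extent when present
  mrnaSpan <- data.frame(
    txId = txIds, geneId = txParent,
    chrom = as.character(GenomicRanges::seqnames(mrna)),
    start = GenomicRanges::start(mrna), end = GenomicRanges::end(mrna),
    strand = as.character(GenomicRanges::strand(mrna)),
    stringsAsFactors = FALSE)
  spans <- if (nrow(mrnaSpan)) mrnaSpan else do.call(rbind, spanRows)
  cdsIndex <- do.call(rbind, idxRows)
  if (is.null(cdsIndex)) {
    cdsIndex <- data.frame(chrom = character(), gpos = integer(),
                           txId = character(), geneId = character(),
                           strand = character(), codon = character(),
                           within = integer(), deg = integer(),
                           stringsAsFactors = FALSE)
  }
  cdsIndex$key <- siteKey(cdsIndex$chrom, cdsIndex$gpos)
  structure(list(seqs = seqs, spans = spans, cdsIndex = cdsIndex,
                 flankBp = as.integer(flankBp), geneticCode = gc),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", length(x$seqs), "sequences,",
      length(unique(x$spans$txId)), "transcripts,",
      nrow(x$cdsIndex), "coding positions\n")
  invisible(x)
}

refBaseAt <- function(ann, chrom, pos) {
  bad <- !(chrom %in% names(ann$seqs))
  if (any(bad)) stop("position outside any sequence: ", chrom[bad][1])
  w <- Biostrings::width(ann$seqs)[match(chrom, names(ann$seqs))]
  if (any(pos < 1 | pos > w)) {
    i <- which(pos < 1 | pos > w)[1]
    stop(sprintf("position outside any sequence: %s:%d", chrom[i], pos[i]))
  }
  as.character(Biostrings::subseq(ann$seqs[chrom], start = pos, width = 1L))
}

## Region class per position: CDS > intron > upstream > downstream >
## intergenic.  Upstream/downstream are strand-aware windows of flankBp
## around the transcript span.
regionOf <- function(ann, chrom, pos) {
  n <- length(pos)
  region <- rep("intergenic", n)
  sp <- ann$spans
  if (nrow(sp) == 0) return(region)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  txg <- GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(sp$start, sp$end))
  upg <- GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(
    ifelse(sp$strand == "+", pmax(1L, sp$start - ann$flankBp), sp$end + 1L),
    ifelse(sp$strand == "+", sp$start - 1L, sp$end + ann$flankBp)))
  dng <- GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(
    ifelse(sp$strand == "+", sp$end + 1L, pmax(1L, sp$start - ann$flankBp)),
    ifelse(sp$strand == "+", sp$end + ann$flankBp, sp$start - 1L)))
  region[GenomicRanges::countOverlaps(q, dng) > 0] <- "downstream"
  region[GenomicRanges::countOverlaps(q, upg) > 0] <- "upstream"
  region[GenomicRanges::countOverlaps(q, txg) > 0] <- "intron"
  region[siteKey(chrom, pos) %in% ann$cdsIndex$key] <- "CDS"
  region
}

#' Classify a genomic site
#'
#' @param ann a `GenomeAnnotation` from [loadAnnotation()].
#' @param chrom,pos site coordinates (1-based).
#' @return a one-row data.frame with region class, gene/strand/codon context
#'   when coding, and site degeneracy (4 = four-fold degenerate; any
#'   substitution is synonymous).
#' @export
classifySite <- function(ann, chrom, pos) {
  refBaseAt(ann, chrom, pos)  # bounds check
  region <- regionOf(ann, chrom, pos)
  hits <- ann$cdsIndex[ann$cdsIndex$key == siteKey(chrom, pos), , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(chrom = chrom, pos = pos, region = region,
                      geneId = NA_character_, strand = NA_character_,
                      codon = NA_character_, codonPos = NA_integer_,
                      degeneracy = NA_integer_, stringsAsFactors = FALSE))
  }
  ## four-fold status requires unanimity over transcripts overlapping here
  deg <- min(hits$deg)
  data.frame(chrom = chrom, pos = pos, region = region,
             geneId = hits$geneId[1], strand = hits$strand[1],
             codon = hits$codon[1], codonPos = hits$within[1],
             degeneracy = deg, stringsAsFactors = FALSE)
}

## Vectorized per-variant effect; the workhorse behind classifyVariant()
## and the pipeline's annotation stage.
variantEffects <- function(ann, chrom, pos, ref, alt) {
  refG <- refBaseAt(ann, chrom, pos)
  bad <- which(refG != ref)
  if (length(bad)) {
    stop(sprintf("REF mismatch at %s:%d (VCF %s, reference %s)",
                 chrom[bad[1]], pos[bad[1]], ref[bad[1]], refG[bad[1]]))
  }
  key <- siteKey(chrom, pos)
  idx <- ann$cdsIndex
  hit <- which(idx$key %in% key)
  effect <- rep("noncoding", length(pos))
  if (length(hit)) {
    m <- match(idx$key[hit], key)
    txRef <- ifelse(idx$strand[hit] == "-", chartr("ACGT", "TGCA", ref[m]),
                    ref[m])
    txAlt <- ifelse(idx$strand[hit] == "-", chartr("ACGT", "TGCA", alt[m]),
                    alt[m])
    cod <- idx$codon[hit]; w <- idx$within[hit]
    altCod <- paste0(substr(cod, 1, w - 1), txAlt,
                     substr(cod, pmin(w + 1, 4), 3))
    gc <- ann$geneticCode
    aaRef <- unname(gc[cod]); aaAlt <- unname(gc[altCod])
    eff <- ifelse(aaRef != "*" & aaAlt == "*", "stopgain",
           ifelse(aaRef == "*" & aaAlt != "*", "stoploss",
           ifelse(aaRef == aaAlt, "synonymous", "nonsynonymous")))
    ## most severe effect across overlapping transcripts
    sev <- tapply(EFFECT_SEVERITY[eff], m, max)
    sidx <- as.integer(names(sev))
    effect[sidx] <- names(EFFECT_SEVERITY)[match(sev, EFFECT_SEVERITY)]
  }
  effect
}

#' Classify a single variant's coding effect
#'
#' Overlapping transcripts are resolved to the most severe effect
#' (stopgain > stoploss > nonsynonymous > synonymous); minus-strand codons
#' are read on the reverse complement.  A REF allele that does not match
#' the reference sequence is an error naming the site.
#'
#' @param ann a `GenomeAnnotation`.
#' @param chrom,pos,ref,alt the variant.
#' @return one of "synonymous", "nonsynonymous", "stopgain", "stoploss",
#'   "noncoding".
#' @export
classifyVariant <- function(ann, chrom, pos, ref, alt) {
  variantEffects(ann, chrom, pos, ref, alt)[1]
}

#' Table of four-fold degenerate sites
#'
#' All and only the positions where every one of the three possible
#' substitutions is synonymous in every transcript overlapping the position
#' (a transcript in which the site is intronic, or 4-fold in one reading
#' frame only, vetoes it).
#'
#' @param ann a `GenomeAnnotation`.
#' @return data.frame with columns chrom, pos, sorted.
#' @export
fourfoldSites <- function(ann) {
  idx <- ann$cdsIndex
  if (nrow(idx) == 0) {
    return(data.frame(chrom = character(), pos = integer()))
  }
  if (!anyDuplicated(idx$key)) {
    ## fast path: no position belongs to more than one transcript
    cand <- idx$key[idx$deg == 4L]
    first <- idx[idx$deg == 4L, c("chrom", "gpos")]
    nCds <- setNames(rep(1L, length(cand)), cand)
  } else {
    nCds <- tapply(rep(1L, nrow(idx)), idx$key, sum)
    n4f <- tapply(as.integer(idx$deg == 4L), idx$key, sum)
    cand <- names(nCds)[nCds == n4f & n4f > 0]
    first <- idx[match(cand, idx$key), c("chrom", "gpos")]
  }
  if (!length(cand)) return(data.frame(chrom = character(), pos = integer()))
  ## veto positions overlapped by a transcript span that does not carry them
  ## as (codon-classified) CDS — e.g. an intron of another transcript or a
  ## transcript excluded for a broken reading frame
  sp <- ann$spans
  q <- GenomicRanges::GRanges(first$chrom, IRanges::IRanges(first$gpos,
                                                            first$gpos))
  txg <- GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(sp$start, sp$end))
  nSpan <- GenomicRanges::countOverlaps(q, txg)
  keep <- nSpan == nCds[cand]
  out <- data.frame(chrom = first$chrom[keep], pos = first$gpos[keep],
                    stringsAsFactors = FALSE)
  out <- out[siteOrder(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
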