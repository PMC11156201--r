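## Toy annotated genome for the forward simulator.
##
## The simulator does not mutate arbitrary positions: it draws from
## pre-enumerated candidate sites whose functional class (neutral
## four-fold-degenerate, deleterious missense-like, stopgain) is literally
## true under codon-aware annotation of the emitted FASTA + GFF3.  Genes are
## two-exon (one intron, so GFF3 phase handling is exercised), placed on
## alternating strands and separated by intergenic spacers.

STOP_CODONS <- c("TAA", "TAG", "TGA")

codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
}

.purgescan_cache <- new.env(parent = emptyenv())

## Per-(codon, position-in-codon) lookup of the simulator's mutable-site
## class and the transcript-sense derived alleles of that class.  A position
## is "neutral" when all three substitutions are synonymous (four-fold
## degenerate), "stopgain" when some substitution creates a stop, otherwise
## "deleterious" (missense alleles only).  Positions inside stop codons get
## NA (never used: start/stop codons are excluded from the pools).
codonClassTables <- function() {
  if (!is.null(.purgescan_cache$codonClass)) return(.purgescan_cache$codonClass)
  gc <- codonTable()
  codons <- names(gc)
  cls <- matrix(NA_character_, length(codons), 3, dimnames = list(codons, NULL))
  alts <- matrix(NA_character_, length(codons), 3, dimnames = list(codons, NULL))
  for (cod in codons) {
    aa <- gc[[cod]]
    if (aa == "*") next
    for (w in 1:3) {
      refb <- substr(cod, w, w)
      altb <- setdiff(BASES, refb)
      newAA <- vapply(altb, function(b) {
        nc <- cod
        substr(nc, w, w) <- b
        gc[[nc]]
      }, "")
      syn <- newAA == aa
      stopg <- newAA == "*"
      if (all(syn)) {
        cls[cod, w] <- "neutral"; alts[cod, w] <- paste(altb, collapse = ",")
      } else if (any(stopg)) {
        cls[cod, w] <- "stopgain"; alts[cod, w] <- paste(altb[stopg], collapse = ",")
      } else {
        cls[cod, w] <- "deleterious"
        alts[cod, w] <- paste(altb[!syn], collapse = ",")
      }
    }
  }
  .purgescan_cache$codonClass <- list(codons = codons, class = cls, alts = alts)
  .purgescan_cache$codonClass
}

#' Build a toy annotated genome
#'
#' @param spec list with fields `type` ("genic" or "neutral"),
#'   `chromLengths` (named integer vector), and for genic genomes
#'   `codonsPerGene`, `intronBp`, `spacerBp`.  A "neutral" genome has no
#'   genes; every position is a neutral candidate site (used for
#'   closed-form calibration runs).
#' @param seed integer seed; the genome is a deterministic function of
#'   (spec, seed).
#' @return list with `seqs` (a [Biostrings::DNAStringSet]), `genes` and
#'   `cds` feature tables, and `candidates`, the mutable-site table with
#'   columns chrom, pos, class, alts (comma-separated genomic derived
#'   alleles), geneId.
#' @export
buildToyGenome <- function(spec, seed) {
  set.seed(deriveSeed(seed, "genome"))
  type <- spec$type %||% "genic"
  chromLengths <- spec$chromLengths
  stopifnot(!is.null(names(chromLengths)))

  seqs <- lapply(chromLengths, function(L) sample(BASES, L, replace = TRUE))
  genes <- list(); cds <- list(); cand <- list()

  if (type == "neutral") {
    altMap <- vapply(BASES, function(b) paste(setdiff(BASES, b), collapse = ","), "")
    for (ch in names(chromLengths)) {
      refs <- seqs[[ch]]
      cand[[ch]] <- data.frame(
        chrom = ch, pos = seq_along(refs), class = "neutral",
        alts = unname(altMap[refs]), geneId = NA_character_,
        stringsAsFactors = FALSE)
    }
  } else {
    tables <- codonClassTables()
    codonsPerGene <- spec$codonsPerGene %||% 100L
    intronBp <- spec$intronBp %||% 100L
    spacerBp <- spec$spacerBp %||% 400L
    sense <- setdiff(tables$codons, STOP_CODONS)
    cdsLen <- 3L * codonsPerGene
    footprint <- cdsLen + intronBp
    geneCounter <- 0L
    strandNext <- "+"
    for (ch in names(chromLengths)) {
      L <- chromLengths[[ch]]
      cursor <- spacerBp + 1L
      while (cursor + footprint + spacerBp <= L) {
        geneCounter <- geneCounter + 1L
        gid <- sprintf("gene%04d", geneCounter)
        strand <- strandNext
        strandNext <- if (strand == "+") "-" else "+"
        codons <- c("ATG", sample(sense, codonsPerGene - 2L, replace = TRUE),
                    sample(STOP_CODONS, 1L))
        tx <- strsplit(paste(codons, collapse = ""), "")[[1]]
        ## split the CDS at an arbitrary base offset (exercises phase != 0)
        len1 <- sample(seq(4L, cdsLen - 4L), 1L)
        len2 <- cdsLen - len1
        gStart <- cursor
        gEnd <- cursor + footprint - 1L
        if (strand == "+") {
          gpos <- c(gStart + seq_len(len1) - 1L,
                    gStart + len1 + intronBp + seq_len(len2) - 1L)
          gbase <- tx
          cdsRows <- data.frame(
            chrom = ch, start = c(gStart, gStart + len1 + intronBp),
            end = c(gStart + len1 - 1L, gEnd), strand = strand,
            phase = c(0L, (3L - len1 %% 3L) %% 3L), geneId = gid,
            stringsAsFactors = FALSE)
        } else {
          gpos <- c(gEnd - seq_len(len1) + 1L,
                    gEnd - len1 - intronBp - seq_len(len2) + 1L)
          gbase <- chartr("ACGT", "TGCA", tx)
          cdsRows <- data.frame(
            chrom = ch, start = c(gEnd - len1 + 1L, gStart),
            end = c(gEnd, gStart + len2 - 1L), strand = strand,
            phase = c(0L, (3L - len1 %% 3L) %% 3L), geneId = gid,
            stringsAsFactors = FALSE)
        }
        seqs[[ch]][gpos] <- gbase
        genes[[gid]] <- data.frame(chrom = ch, start = gStart, end = gEnd,
                                   strand = strand, geneId = gid,
                                   stringsAsFactors = FALSE)
        cds[[gid]] <- cdsRows
        cand[[gid]] <- enumerateCodingCandidates(codons, gpos, strand, gid, ch,
                                                 tables)
        cursor <- gEnd + spacerBp + 1L
      }
    }
  }

  seqSet <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(seqSet) <- names(chromLengths)
  candidates <- do.call(rbind, cand)
  rownames(candidates) <- NULL
  o <- siteOrder(candidates$chrom, candidates$pos)
  list(seqs = seqSet,
       genes = if (length(genes)) do.call(rbind, genes) else NULL,
       cds = if (length(cds)) do.call(rbind, cds) else NULL,
       candidates = candidates[o, , drop = FALSE])
}

## Vectorized per-gene candidate enumeration via the codon-class tables.
## `codons` are the gene's codon strings, `gpos` maps transcript position
## (1..3*nCodons) to genomic coordinate.  Internal positions only.
enumerateCodingCandidates <- function(codons, gpos, strand, gid, ch, tables) {
  cdsLen <- 3L * length(codons)
  keep <- seq(4L, cdsLen - 3L)
  ci <- (keep - 1L) %/% 3L
  within <- keep - 3L * ci
  codAt <- codons[ci + 1L]
  idx <- cbind(match(codAt, tables$codons), within)
  cls <- tables$class[idx]
  altsTx <- tables$alts[idx]
  ok <- !is.na(cls)
  altsG <- if (strand == "+") altsTx[ok] else chartr("ACGT", "TGCA", altsTx[ok])
  data.frame(chrom = ch, pos = gpos[keep[ok]], class = cls[ok], alts = altsG,
             geneId = gid, stringsAsFactors = FALSE)
}

## FASTA / GFF3 writers for bundles ------------------------------------------

writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path)
  invisible(path)
}

writeGenomeGff <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ch in names(genome$seqs)) {
    writeLines(sprintf("##sequence-region %s 1 %d", ch,
                       Biostrings::width(genome$seqs[ch])), con)
  }
  if (is.null(genome$genes)) return(invisible(path))
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    mid <- paste0(g$geneId, ".t1")
    writeLines(sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start, g$end, g$strand, g$geneId), con)
    writeLines(sprintf("%s\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom, g$start, g$end, g$strand, mid, g$geneId), con)
    segs <- genome$cds[genome$cds$geneId == g$geneId, ]
    for (j in seq_len(nrow(segs))) {
      writeLines(sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                         segs$chrom[j], segs$start[j], segs$end[j],
                         segs$strand[j], segs$phase[j], mid, mid), con)
    }
  }
  invisible(path)
}
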