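test_that("site classification reads codons, regions and degeneracy", {
  toy <- writeToyAnnotation()
  # a short flank keeps part of the 600 bp toy chromosome intergenic
  ann <- loadAnnotation(toy$fasta, toy$gff, flankBp = 50L)

  # third position of GGA (Gly) is four-fold degenerate
  cs <- classifySite(ann, "chr1", 106L)
  expect_equal(cs$region, "CDS")
  expect_equal(cs$codon, "GGA")
  expect_equal(cs$codonPos, 3L)
  expect_equal(cs$degeneracy, 4L)

  # third position of AAA (Lys) is two-fold, not four-fold
  cs2 <- classifySite(ann, "chr1", 109L)
  expect_equal(cs2$codon, "AAA")
  expect_equal(cs2$degeneracy, 2L)

  # a position inside the minus-strand gene but not in CDS is intronic
  intronPos <- toy$geneB$start + 8L + 5L  # inside the 30 bp intron
  expect_equal(classifySite(ann, "chr1", intronPos)$region, "intron")

  # strand-aware flanks
  expect_equal(classifySite(ann, "chr1", 95L)$region, "upstream")
  expect_equal(classifySite(ann, "chr1", 120L)$region, "downstream")
  expect_equal(classifySite(ann, "chr1", 580L)$region, "intergenic")

  # out-of-range coordinates fail loudly
  expect_error(classifySite(ann, "chr1", 10000L), "outside")
  expect_error(classifySite(ann, "chrX", 10L), "outside")
})

test_that("variant effects follow the codon change, including minus strand", {
  toy <- writeToyAnnotation()
  ann <- loadAnnotation(toy$fasta, toy$gff)

  # CAG -> TAG via C>T at codon position 1 is a stopgain
  expect_equal(classifyVariant(ann, "chr1", 110L, "C", "T"), "stopgain")
  # AAA -> AAG at position 3 is synonymous
  expect_equal(classifyVariant(ann, "chr1", 109L, "A", "G"), "synonymous")
  # GGA -> GAA at position 2 is nonsynonymous
  expect_equal(classifyVariant(ann, "chr1", 105L, "G", "A"), "nonsynonymous")
  # TAA -> CAA destroys the stop codon
  expect_equal(classifyVariant(ann, "chr1", 113L, "T", "C"), "stoploss")

  # minus-strand gene: transcript TGG -> TGA; the transcript G>A at codon
  # position 6 is genomic C>T on the plus strand
  gpos <- toy$gposB[6]
  expect_equal(substr(paste(toy$seq, collapse = ""), gpos, gpos), "C")
  expect_equal(classifyVariant(ann, "chr1", gpos, "C", "T"), "stopgain")
  # and a synonymous change in the same gene: TCC -> TCT (transcript
  # position 12, C>T) is genomic G>A
  gpos12 <- toy$gposB[12]
  expect_equal(classifyVariant(ann, "chr1", gpos12, "G", "A"), "synonymous")

  # REF mismatches are an error naming the site
  expect_error(classifyVariant(ann, "chr1", 110L, "G", "T"), "110")
})

test_that("four-fold site table is exhaustive and unanimous", {
  toy <- writeToyAnnotation()
  ann <- loadAnnotation(toy$fasta, toy$gff)
  ff <- fourfoldSites(ann)
  # gene A contributes GGA position 3; gene B contributes TCC position 3
  expect_setequal(ff$pos, c(106L, toy$gposB[12]))

  # every listed site is synonymous for all three alternatives (exhaustive
  # check through the variant classifier)
  for (i in seq_len(nrow(ff))) {
    ref <- substr(paste(toy$seq, collapse = ""), ff$pos[i], ff$pos[i])
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      expect_equal(classifyVariant(ann, ff$chrom[i], ff$pos[i], ref, alt),
                   "synonymous")
    }
  }
})

test_that("strand symmetry: the reverse-complemented genome classifies
           identically at mapped coordinates", {
  toy <- writeToyAnnotation()
  ann <- loadAnnotation(toy$fasta, toy$gff)
  L <- length(toy$seq)
  # build the reverse-complement genome with flipped features
  dir <- tempfile("rc_"); dir.create(dir)
  rcseq <- rev(chartr("ACGT", "TGCA", toy$seq))
  fa <- file.path(dir, "rc.fa")
  writeLines(c(">chr1", paste(rcseq, collapse = "")), fa)
  gffLines <- readLines(toy$gff)
  flip <- function(line) {
    f <- strsplit(line, "\t")[[1]]
    if (length(f) < 8) return(line)
    s <- as.integer(f[4]); e <- as.integer(f[5])
    f[4] <- as.character(L - e + 1L); f[5] <- as.character(L - s + 1L)
    f[7] <- if (f[7] == "+") "-" else "+"
    paste(f, collapse = "\t")
  }
  gff <- file.path(dir, "rc.gff3")
  writeLines(vapply(gffLines, flip, ""), gff)
  annRC <- loadAnnotation(fa, gff)

  ffA <- fourfoldSites(ann)
  ffB <- fourfoldSites(annRC)
  expect_setequal(L - ffA$pos + 1L, ffB$pos)

  # variant effects map through the complement
  pos <- 110L
  expect_equal(
    classifyVariant(annRC, "chr1", L - pos + 1L, "G", "A"),  # complement C>T
    classifyVariant(ann, "chr1", pos, "C", "T"))
})

test_that("broken reading frames are excluded from codon classes with a
           warning and veto four-fold status", {
  toy <- writeToyAnnotation()
  gffLines <- readLines(toy$gff)
  # corrupt gene A's CDS end so its length is not a multiple of 3
  gffLines <- sub("CDS\t101\t115", "CDS\t101\t114", gffLines)
  gff2 <- file.path(tempfile("bad_"), "bad.gff3")
  dir.create(dirname(gff2))
  writeLines(gffLines, gff2)
  expect_warning(ann <- loadAnnotation(toy$fasta, gff2), "divisible by 3")
  ff <- fourfoldSites(ann)
  expect_false(106L %in% ff$pos)      # gene A vetoed
  expect_true(toy$gposB[12] %in% ff$pos)  # gene B unaffected
})
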