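# Small in-code fixtures shared across test files.

# Hand-built GenotypeDataset: `dosage` is sites x samples.
makeDataset <- function(dosage, chrom = NULL, pos = NULL, ref = NULL,
                        alt = NULL, depth = NULL) {
  n <- nrow(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("s%02d", seq_len(ncol(dosage)))
  GenotypeDataset(dosage,
                  chrom = chrom %||% rep("chr1", n),
                  pos = pos %||% (seq_len(n) * 100L),
                  ref = ref %||% rep("A", n),
                  alt = alt %||% rep("G", n),
                  depth = depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny two-gene genome written to FASTA + GFF3: a plus-strand single-exon
# gene and a minus-strand two-exon gene with a non-zero phase, embedded in
# a fixed random background.  Returns the file paths plus the coordinates
# the tests assert against.
writeToyAnnotation <- function(dir = tempfile("ann_")) {
  dir.create(dir)
  set.seed(42)
  L <- 600L
  seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  # gene A (+): ATG GGA AAA CAG TAA at 101..115
  geneA <- strsplit("ATGGGAAAACAGTAA", "")[[1]]
  seqv[101:115] <- geneA
  # gene B (-): transcript ATG TGG CAT TCC TAA; genomic = revcomp, split
  # into two CDS exons with a 30 bp intron after 7 coding bases
  txB <- strsplit("ATGTGGCATTCCTAA", "")[[1]]
  len1 <- 7L; len2 <- length(txB) - len1
  gStart <- 301L
  intron <- 30L
  gEnd <- gStart + length(txB) + intron - 1L
  # translation-order exon 1 sits at the genomic right end
  gposB <- c(gEnd - seq_len(len1) + 1L,
             gEnd - len1 - intron - seq_len(len2) + 1L)
  seqv[gposB] <- chartr("ACGT", "TGCA", txB)
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chr1", paste(seqv, collapse = "")), fa)
  gff <- file.path(dir, "toy.gff3")
  phase2 <- (3L - len1 %% 3L) %% 3L
  writeLines(c(
    "##gff-version 3",
    sprintf("chr1\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=gA", 101L, 115L),
    sprintf("chr1\ttoy\tmRNA\t%d\t%d\t.\t+\t.\tID=gA.t1;Parent=gA", 101L, 115L),
    sprintf("chr1\ttoy\tCDS\t%d\t%d\t.\t+\t0\tID=gA.c;Parent=gA.t1", 101L, 115L),
    sprintf("chr1\ttoy\tgene\t%d\t%d\t.\t-\t.\tID=gB", gStart, gEnd),
    sprintf("chr1\ttoy\tmRNA\t%d\t%d\t.\t-\t.\tID=gB.t1;Parent=gB", gStart, gEnd),
    sprintf("chr1\ttoy\tCDS\t%d\t%d\t.\t-\t0\tID=gB.c1;Parent=gB.t1",
            gEnd - len1 + 1L, gEnd),
    sprintf("chr1\ttoy\tCDS\t%d\t%d\t.\t-\t%d\tID=gB.c2;Parent=gB.t1",
            gStart, gStart + len2 - 1L, phase2)), gff)
  list(fasta = fa, gff = gff, seq = seqv, gposB = gposB, txB = txB,
       geneA = list(start = 101L, end = 115L),
       geneB = list(start = gStart, end = gEnd))
}

# Minimal multi-record VCF text fixture.
writeToyVCF <- function(dir = tempfile("vcf_")) {
  dir.create(dir)
  path <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t.\t.\t.\tGT:DP\t0/0:9\t0/1:8\t1/1:7",
    "chr1\t200\t.\tC\tT\t.\t.\t.\tGT:DP\t./.:.\t0/0:2\t0/1:9",
    "chr1\t300\t.\tG\tA,T\t.\t.\t.\tGT:DP\t0/1:9\t0/2:9\t0/0:9",
    "chr1\t400\t.\tGTT\tG\t.\t.\t.\tGT:DP\t0/0:9\t0/1:9\t0/0:9",
    "chr2\t50\t.\tT\tC\t.\t.\t.\tGT:DP\t1/1:9\t0/1:9\t0/0:9"), path)
  path
}
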