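#' Write a complete simulated input bundle
#'
#' Emits everything the analysis pipeline consumes: a VCF of the sampled
#' genotypes, the toy reference FASTA and its GFF3 gene models (whose codons
#' make the simulated site classes literally true under codon-aware
#' annotation), the outgroup-allele table, the clade map, the dnSNP site
#' list (truth deleterious sites), and the full truth table.
#'
#' Before writing, every truth record is checked against the reference
#' sequence; an inconsistency is an error naming the site.
#'
#' @param sim result of [simulatePopulations()].
#' @param outdir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
writeBundle <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- sim$dataset; truth <- sim$truth; genome <- sim$genome

  if (nSites(ds) > 0) {
    refAt <- as.character(Biostrings::subseq(genome$seqs[truth$chrom],
                                             start = truth$pos, width = 1L))
    bad <- which(refAt != truth$ancestral)
    if (length(bad)) {
      stop(sprintf("truth/reference inconsistency at %s:%d",
                   truth$chrom[bad[1]], truth$pos[bad[1]]))
    }
  }

  paths <- c(
    vcf = file.path(outdir, "variants.vcf"),
    fasta = file.path(outdir, "reference.fa"),
    gff = file.path(outdir, "annotation.gff3"),
    outgroups = file.path(outdir, "outgroups.tsv"),
    clades = file.path(outdir, "clades.tsv"),
    dnsnp = file.path(outdir, "dnsnp_sites.tsv"),
    truth = file.path(outdir, "truth.tsv"))

  contigs <- setNames(Biostrings::width(genome$seqs), names(genome$seqs))
  writeVCF(ds, paths[["vcf"]], contigs = contigs)
  writeGenomeFasta(genome, paths[["fasta"]])
  writeGenomeGff(genome, paths[["gff"]])

  og <- data.frame(chrom = truth$chrom, pos = truth$pos,
                   og1 = truth$og1, og2 = truth$og2)
  write.table(og, paths[["outgroups"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$cladeMap, paths[["clades"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  dn <- truth[truth$class == "deleterious", c("chrom", "pos")]
  write.table(dn, paths[["dnsnp"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  tr <- truth
  attr(tr, "planted") <- NULL
  write.table(tr, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
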