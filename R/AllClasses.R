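#' GenotypeDataset: biallelic SNP genotypes for many samples
#'
#' The universal substrate of the pipeline: a sites x samples matrix of
#' derived-from-reference ("alt") allele dosages in \{0, 1, 2, NA\} together
#' with per-site metadata (chromosome, 1-based position, reference and
#' alternate single-base alleles) and an optional per-call depth matrix.
#' Sites are kept sorted by (chrom, pos) and unique; only biallelic SNPs are
#' representable.
#'
#' @slot dosage integer matrix, sites x samples, values 0/1/2/NA.
#' @slot chrom character vector of chromosome names per site.
#' @slot pos integer vector of 1-based positions per site.
#' @slot ref,alt character vectors of single-base alleles per site.
#' @slot depth numeric matrix of per-call depths (same dim as `dosage`) or
#'   `NULL` when depth information is unavailable.
#' @exportClass GenotypeDataset
setClass("GenotypeDataset",
  representation(
    dosage = "matrix",
    chrom = "character",
    pos = "integer",
    ref = "character",
    alt = "character",
    depth = "ANY"
  )
)

setValidity("GenotypeDataset", function(object) {
  msg <- character()
  n <- nrow(object@dosage)
  if (length(object@chrom) != n) msg <- c(msg, "chrom length != number of sites")
  if (length(object@pos) != n) msg <- c(msg, "pos length != number of sites")
  if (length(object@ref) != n) msg <- c(msg, "ref length != number of sites")
  if (length(object@alt) != n) msg <- c(msg, "alt length != number of sites")
  if (is.null(colnames(object@dosage)) && ncol(object@dosage) > 0)
    msg <- c(msg, "dosage matrix must have sample ids as column names")
  d <- object@dosage
  if (length(d) > 0 && !all(d[!is.na(d)] %in% 0:2))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (n > 1) {
    o <- siteOrder(object@chrom, object@pos)
    if (!identical(o, seq_len(n))) msg <- c(msg, "sites must be sorted by (chrom, pos)")
    if (anyDuplicated(siteKey(object@chrom, object@pos)))
      msg <- c(msg, "duplicate (chrom, pos) sites")
  }
  if (!is.null(object@depth) &&
      !identical(dim(object@depth), dim(object@dosage)))
    msg <- c(msg, "depth matrix dimensions must match dosage")
  if (n > 0) {
    ok <- object@ref %in% BASES & object@alt %in% BASES & object@ref != object@alt
    if (!all(ok)) msg <- c(msg, "ref/alt must be distinct single bases (biallelic SNPs only)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeDataset
#'
#' Sites are sorted by (chrom, pos) on construction; validity enforces
#' uniqueness and the biallelic-SNP contract.
#'
#' @param dosage sites x samples matrix of alt-allele dosages (0/1/2/NA);
#'   column names are sample ids.
#' @param chrom,pos,ref,alt per-site metadata vectors.
#' @param depth optional per-call depth matrix.
#' @return a [GenotypeDataset-class] object.
#' @examples
#' gd <- GenotypeDataset(matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'                              dimnames = list(NULL, c("s1", "s2"))),
#'                       chrom = c("chr1", "chr1"), pos = c(10L, 5L),
#'                       ref = c("A", "C"), alt = c("G", "T"))
#' nSites(gd)
#' @export
GenotypeDataset <- function(dosage, chrom, pos, ref, alt, depth = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  o <- siteOrder(as.character(chrom), as.integer(pos))
  new("GenotypeDataset",
      dosage = dosage[o, , drop = FALSE],
      chrom = as.character(chrom)[o],
      pos = as.integer(pos)[o],
      ref = as.character(ref)[o],
      alt = as.character(alt)[o],
      depth = if (is.null(depth)) NULL else as.matrix(depth)[o, , drop = FALSE])
}

#' SimulationConfig: demographic and selection scenario for the simulator
#'
#' Describes a forward-time Wright-Fisher scenario: a toy genome
#' specification, per-population epoch plans (sizes, selfing rates, splits),
#' mutation rates for the neutral (four-fold-degenerate-like), deleterious
#' missense-like and stopgain-like site classes with their selection and
#' dominance coefficients, outgroup divergence, and the diploid sample sizes
#' drawn at the final generation.
#'
#' @slot seed master integer seed; identical config + seed gives bit-identical
#'   output bundles.
#' @slot nGenerations total number of generations simulated.
#' @slot populations list of population plans; each a list with `name`,
#'   `parent` (`NA` for the root), `splitGen`, a data.frame `epochs` with
#'   columns start/end/N tiling `[splitGen, nGenerations]`, and `selfing`.
#' @slot muNeutral,muDel,muLof per-candidate-site per-generation mutation
#'   rates for the three site classes.
#' @slot sDel,hDel,sLof,hLof selection and dominance coefficients of the
#'   deleterious and stopgain classes.
#' @slot outgroupDivergence expected substitutions per site on each outgroup
#'   lineage.
#' @slot sampleSizes named integer vector of diploids sampled per population.
#' @slot mode `"independent"` (free recombination) or `"block"` (one
#'   non-recombining segment).
#' @slot genomeSpec list describing the toy genome (see [buildToyGenome()]).
#' @slot planted data.frame of planted mutations (columns pop, gen, chrom,
#'   targetPos, s, h, copies), possibly empty.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nGenerations = "integer",
    populations = "list",
    muNeutral = "numeric",
    muDel = "numeric",
    muLof = "numeric",
    sDel = "numeric",
    hDel = "numeric",
    sLof = "numeric",
    hLof = "numeric",
    outgroupDivergence = "numeric",
    sampleSizes = "integer",
    mode = "character",
    genomeSpec = "list",
    planted = "data.frame"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  for (r in c(muNeutral = object@muNeutral, muDel = object@muDel,
              muLof = object@muLof)) {
    if (r < 0 || r >= 1) msg <- c(msg, "mutation rates must lie in [0, 1)")
  }
  for (s in c(object@sDel, object@sLof)) if (s < 0 || s > 1)
    msg <- c(msg, "class selection coefficients must lie in [0, 1]")
  for (h in c(object@hDel, object@hLof)) if (h < 0 || h > 1)
    msg <- c(msg, "dominance coefficients must lie in [0, 1]")
  if (object@outgroupDivergence < 0)
    msg <- c(msg, "outgroup divergence must be non-negative")
  if (!object@mode %in% c("independent", "block"))
    msg <- c(msg, "mode must be 'independent' or 'block'")
  popNames <- vapply(object@populations, function(p) p$name, "")
  if (anyDuplicated(popNames)) msg <- c(msg, "duplicate population names")
  for (p in object@populations) {
    ep <- p$epochs
    if (!all(c("start", "end", "N") %in% names(ep))) {
      msg <- c(msg, sprintf("population '%s': epochs need start/end/N", p$name))
      next
    }
    if (any(ep$N < 2))
      msg <- c(msg, sprintf("population '%s': N must be >= 2 in every epoch", p$name))
    start0 <- if (is.na(p$parent)) 0L else as.integer(p$splitGen)
    if (ep$start[1] != start0 ||
        ep$end[nrow(ep)] != object@nGenerations ||
        (nrow(ep) > 1 && !all(ep$start[-1] == ep$end[-nrow(ep)])))
      msg <- c(msg, sprintf(
        "population '%s': epochs must tile [%d, %d] without gaps or overlap",
        p$name, start0, object@nGenerations))
    if (p$selfing < 0 || p$selfing > 1)
      msg <- c(msg, sprintf("population '%s': selfing rate must lie in [0, 1]", p$name))
    if (!is.na(p$parent) && !p$parent %in% popNames)
      msg <- c(msg, sprintf("population '%s': unknown parent '%s'", p$name, p$parent))
  }
  if (!all(names(object@sampleSizes) %in% popNames))
    msg <- c(msg, "sampleSizes refer to unknown populations")
  if (length(msg)) msg else TRUE
})

#' ROHParams: runs-of-homozygosity detection parameters
#'
#' Defaults reproduce the PLINK `--homozyg` parameterization commonly used in
#' resequencing studies: scanning windows of `windowSnp` SNPs tolerating
#' `windowHet` heterozygous and `windowMissing` missing calls, SNP
#' qualification when at least `windowThreshold` of spanning windows are
#' homozygous, and final segments of at least `minSnps` SNPs and `minKb` kb
#' with inter-SNP gaps at most `gapKb` kb and at least one SNP per
#' `densityKb` kb.  Note `gapKb` and `densityKb` are kilobases.
#'
#' @slot densityKb,gapKb,minKb,minSnps,windowHet,windowSnp,windowMissing,windowThreshold
#'   numeric scalars, see description.
#' @exportClass ROHParams
setClass("ROHParams",
  representation(
    densityKb = "numeric", gapKb = "numeric", minKb = "numeric",
    minSnps = "numeric", windowHet = "numeric", windowSnp = "numeric",
    windowMissing = "numeric", windowThreshold = "numeric"
  )
)

setValidity("ROHParams", function(object) {
  msg <- character()
  vals <- c(object@densityKb, object@gapKb, object@minKb, object@minSnps,
            object@windowSnp, object@windowThreshold)
  if (any(vals <= 0)) msg <- c(msg, "parameters must be positive")
  if (object@windowHet < 0 || object@windowMissing < 0)
    msg <- c(msg, "window tolerances must be non-negative")
  if (object@windowHet > object@windowSnp)
    msg <- c(msg, "windowHet must not exceed windowSnp")
  if (object@windowThreshold > 1)
    msg <- c(msg, "windowThreshold is a fraction in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct ROH detection parameters
#'
#' @param densityKb minimum SNP density within a run: at most `densityKb` kb
#'   per SNP (default 50).
#' @param gapKb maximum gap between consecutive SNPs in a run, kb (default 1000).
#' @param minKb minimum run length in kb (default 30).
#' @param minSnps minimum number of SNPs in a run (default 40).
#' @param windowHet maximum heterozygous calls per homozygous window (default 2).
#' @param windowSnp scanning window size in SNPs (default 40).
#' @param windowMissing maximum missing calls per homozygous window (default 10).
#' @param windowThreshold minimum fraction of homozygous spanning windows for
#'   a SNP to qualify (default 0.05).
#' @return a [ROHParams-class] object.
#' @export
rohParams <- function(densityKb = 50, gapKb = 1000, minKb = 30, minSnps = 40,
                      windowHet = 2, windowSnp = 40, windowMissing = 10,
                      windowThreshold = 0.05) {
  new("ROHParams", densityKb = densityKb, gapKb = gapKb, minKb = minKb,
      minSnps = minSnps, windowHet = windowHet, windowSnp = windowSnp,
      windowMissing = windowMissing, windowThreshold = windowThreshold)
}
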