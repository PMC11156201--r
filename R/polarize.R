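## Ancestral/derived polarization from two single-genome outgroups.
##
## Rules (applied in order, per site):
##  (1) the two outgroup alleles agree and match one focal allele: that
##      allele is ancestral, the other focal allele derived ("resolved");
##  (2) they agree on a third allele carried by neither focal allele: both
##      focal alleles are derived relative to it ("resolved_external" —
##      counted as derived for load purposes, excluded from the unfolded
##      SFS whose frequency axis needs a single derived allele);
##  (3) outgroups disagree, or either is missing: "unresolved"; such sites
##      carry no derived-allele counts downstream.

#' Polarize sites against two outgroup alleles
#'
#' Vectorized over sites; the rule is symmetric in the two outgroups.
#'
#' @param ref,alt focal alleles (distinct single bases).
#' @param og1,og2 outgroup alleles (single bases or NA).
#' @return data.frame with columns status ("resolved", "resolved_external",
#'   "unresolved"), ancestral, derived (NA unless resolved).
#' @export
polarizeSites <- function(ref, alt, og1, og2) {
  ok <- function(x) is.na(x) | x %in% BASES
  if (!all(ok(og1) & ok(og2)) || !all(ref %in% BASES & alt %in% BASES)) {
    stop("non-nucleotide allele in polarization input")
  }
  if (any(ref == alt)) stop("focal alleles must be distinct")
  n <- length(ref)
  status <- rep("unresolved", n)
  ancestral <- rep(NA_character_, n)
  derived <- rep(NA_character_, n)
  agree <- !is.na(og1) & !is.na(og2) & og1 == og2
  isRef <- agree & og1 == ref
  isAlt <- agree & og1 == alt
  ext <- agree & !isRef & !isAlt
  status[isRef | isAlt] <- "resolved"
  status[ext] <- "resolved_external"
  ancestral[isRef] <- ref[isRef]; derived[isRef] <- alt[isRef]
  ancestral[isAlt] <- alt[isAlt]; derived[isAlt] <- ref[isAlt]
  ancestral[ext] <- og1[ext]  # both focal alleles derived
  data.frame(status = status, ancestral = ancestral, derived = derived,
             stringsAsFactors = FALSE)
}

#' Polarize a single site
#'
#' @param ref,alt,og1,og2 single alleles; see [polarizeSites()].
#' @return one-row data.frame (status, ancestral, derived).
#' @export
polarizeSite <- function(ref, alt, og1, og2) polarizeSites(ref, alt, og1, og2)

#' Polarize a whole dataset and derive per-sample derived-allele dosages
#'
#' Sites without an outgroup row are unresolved.  The derived dosage equals
#' the alt dosage when alt is derived, `2 - dosage` when ref is derived,
#' and a constant 2 per called genotype at resolved_external sites (both
#' focal alleles derived).  Unresolved sites get NA dosages.
#'
#' @param ds a [GenotypeDataset-class].
#' @param outgroups data.frame with columns chrom, pos, og1, og2 (duplicate
#'   sites are an error).
#' @return list with `sites` (per-site chrom, pos, status, ancestral,
#'   derived) and `derivedDosage` (sites x samples matrix; NA where the
#'   call is missing or the site unresolved).
#' @export
polarizeDataset <- function(ds, outgroups) {
  if (anyDuplicated(siteKey(outgroups$chrom, outgroups$pos)))
    stop("duplicate (chrom, pos) rows in outgroup table")
  key <- siteKey(ds@chrom, ds@pos)
  m <- match(key, siteKey(outgroups$chrom, outgroups$pos))
  og1 <- outgroups$og1[m]; og2 <- outgroups$og2[m]
  pol <- polarizeSites(ds@ref, ds@alt, og1, og2)
  d <- dosages(ds)
  dd <- matrix(NA_integer_, nrow(d), ncol(d), dimnames = dimnames(d))
  refDer <- pol$status == "resolved" & pol$derived == ds@ref
  altDer <- pol$status == "resolved" & pol$derived == ds@alt
  ext <- pol$status == "resolved_external"
  dd[altDer, ] <- d[altDer, ]
  dd[refDer, ] <- 2L - d[refDer, ]
  dd[ext, ] <- ifelse(is.na(d[ext, , drop = FALSE]), NA_integer_, 2L)
  dd[is.na(d)] <- NA_integer_
  sites <- cbind(data.frame(chrom = ds@chrom, pos = ds@pos,
                            stringsAsFactors = FALSE), pol)
  list(sites = sites, derivedDosage = dd)
}
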