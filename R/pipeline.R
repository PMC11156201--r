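## Pipeline orchestration: annotate -> polarize -> stats -> roh -> load ->
## sweeps from one declarative configuration, with TSV outputs and a JSON
## manifest of parameters and checksums.

#' Build a pipeline configuration
#'
#' @param vcf,fasta,gff,outgroups,clades input paths (all required).
#' @param dnsnp optional deleterious-site list TSV (chrom, pos); when
#'   absent, nonsynonymous sites stand in with a warning.
#' @param track2 optional external per-window score track TSV (an XP-CLR
#'   style stand-in) enabling the sweep stage.
#' @param outdir output directory.
#' @param stages stages to run, a subset of
#'   c("import", "annotate", "polarize", "stats", "roh", "load", "sweeps").
#' @param filter list(minCalled, minMaf, minDepth) for [filterVariants()].
#' @param piWindowBp,piStepBp sliding-window geometry for pi and FST scans.
#' @param pisWindowBp nonoverlapping window size for four-fold diversity.
#' @param fstMinSnps minimum SNPs per FST window.
#' @param projectionN SFS projection (haplotypes).
#' @param dafThreshold rare-variant DAF threshold.
#' @param roh a [ROHParams-class].
#' @param sweepQ outlier quantile for the sweep stage.
#' @return validated configuration list for [runPipeline()].
#' @export
pipelineConfig <- function(vcf, fasta, gff, outgroups, clades, dnsnp = NULL,
                           track2 = NULL, outdir = tempfile("purgescan_"),
                           stages = c("import", "annotate", "polarize",
                                      "stats", "roh", "load", "sweeps"),
                           filter = list(minCalled = 0.8, minMaf = 0.05,
                                         minDepth = 3),
                           piWindowBp = 50000L, piStepBp = 10000L,
                           pisWindowBp = 10000L, fstMinSnps = 10L,
                           projectionN = 20L, dafThreshold = 0.1,
                           roh = rohParams(), sweepQ = 0.05) {
  cfg <- list(vcf = vcf, fasta = fasta, gff = gff, outgroups = outgroups,
              clades = clades, dnsnp = dnsnp, track2 = track2,
              outdir = outdir, stages = stages, filter = filter,
              piWindowBp = piWindowBp, piStepBp = piStepBp,
              pisWindowBp = pisWindowBp, fstMinSnps = fstMinSnps,
              projectionN = projectionN, dafThreshold = dafThreshold,
              roh = roh, sweepQ = sweepQ)
  required <- c("vcf", "fasta", "gff", "outgroups", "clades")
  for (f in required) {
    if (is.null(cfg[[f]])) stop("pipeline config missing input: ", f)
    if (!file.exists(cfg[[f]])) stop("input file does not exist: ", cfg[[f]])
  }
  for (f in c("dnsnp", "track2")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("input file does not exist: ", cfg[[f]])
  }
  cfg
}

#' Pipeline configuration for a simulated bundle directory
#'
#' @param dir directory written by [writeBundle()].
#' @param ... overrides passed to [pipelineConfig()].
#' @export
bundleConfig <- function(dir, ...) {
  pipelineConfig(vcf = file.path(dir, "variants.vcf"),
                 fasta = file.path(dir, "reference.fa"),
                 gff = file.path(dir, "annotation.gff3"),
                 outgroups = file.path(dir, "outgroups.tsv"),
                 clades = file.path(dir, "clades.tsv"),
                 dnsnp = file.path(dir, "dnsnp_sites.tsv"), ...)
}

writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order, writes one TSV per result plus
#' a JSON manifest (package version, parameters, input and output
#' checksums) and a human-readable summary.  The run is deterministic:
#' identical inputs give byte-identical outputs.
#'
#' @param config from [pipelineConfig()] or [bundleConfig()].
#' @return (invisibly) a list of in-memory stage results.
#' @export
runPipeline <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)
  outputs <- character(0)
  st <- function(name) name %in% config$stages

  cladeMap <- readCladeMap(config$clades)

  if (st("import")) {
    raw <- readVCF(config$vcf)
    fl <- filterVariants(raw, minCalled = config$filter$minCalled,
                         minMaf = config$filter$minMaf,
                         minDepth = config$filter$minDepth)
    res$dataset <- fl$dataset
    res$filterCounts <- fl$counts
    missing <- setdiff(sampleIds(res$dataset), cladeMap$sample)
    if (length(missing)) stop("samples absent from clade map: ",
                              paste(missing, collapse = ", "))
  }
  ds <- res$dataset
  chromLengths <- NULL

  if (st("annotate")) {
    ann <- loadAnnotation(config$fasta, config$gff)
    res$annotation <- ann
    chromLengths <- setNames(Biostrings::width(ann$seqs), names(ann$seqs))
    res$fourfold <- fourfoldSites(ann)
    if (nSites(ds) > 0) {
      si <- siteInfo(ds)
      res$effects <- data.frame(
        si, region = regionOf(ann, si$chrom, si$pos),
        effect = variantEffects(ann, si$chrom, si$pos, si$ref, si$alt),
        stringsAsFactors = FALSE)
      outputs["site_effects"] <- writeTsv(
        res$effects, file.path(config$outdir, "site_effects.tsv"))
    }
    if (!is.null(config$dnsnp)) {
      res$dnsnp <- readSiteList(config$dnsnp)
    } else {
      warning("no dnSNP list supplied; using all nonsynonymous sites")
      res$dnsnp <- res$effects[res$effects$effect == "nonsynonymous",
                               c("chrom", "pos")]
    }
    outputs["fourfold_sites"] <- writeTsv(
      res$fourfold, file.path(config$outdir, "fourfold_sites.tsv"))
  }

  if (st("polarize")) {
    og <- readOutgroupTable(config$outgroups)
    pol <- polarizeDataset(ds, og)
    res$polarized <- pol
    outputs["polarization"] <- writeTsv(
      pol$sites, file.path(config$outdir, "polarization.tsv"))
  }

  if (st("stats")) {
    clades <- split(cladeMap$sample, cladeMap$clade)
    altGroups <- split(cladeMap$sample, cladeMap$altitude)
    ## four-fold diversity per clade and per altitude group,
    ## nonoverlapping windows
    groups <- c(clades, altGroups)
    pisRows <- lapply(names(groups), function(g) {
      tr <- windowedPi(ds, samples = groups[[g]],
                       windowBp = config$pisWindowBp,
                       stepBp = config$pisWindowBp,
                       chromLengths = chromLengths, sites = res$fourfold)
      data.frame(group = g, medianPis = median(tr$value, na.rm = TRUE),
                 meanPis = mean(tr$value, na.rm = TRUE),
                 nWindows = sum(!is.na(tr$value)), stringsAsFactors = FALSE)
    })
    res$pis <- do.call(rbind, pisRows)
    outputs["pis_by_group"] <- writeTsv(
      res$pis, file.path(config$outdir, "pis_by_group.tsv"))

    if (all(c("high", "low") %in% names(altGroups)) &&
        all(lengths(altGroups) >= 2)) {
      res$fst <- windowedFst(ds, altGroups$high, altGroups$low,
                             windowBp = config$piWindowBp,
                             stepBp = config$piStepBp,
                             chromLengths = chromLengths,
                             minSnps = config$fstMinSnps)
      outputs["fst_high_vs_low"] <- writeTsv(
        res$fst, file.path(config$outdir, "fst_high_vs_low.tsv"))
    }

    ## class-stratified unfolded SFS per clade and altitude group
    keys <- siteKey(ds@chrom, ds@pos)
    resolved <- res$polarized$sites$status == "resolved"
    classSites <- list(
      fourfold = keys %in% siteKey(res$fourfold$chrom, res$fourfold$pos),
      dnsnp = keys %in% siteKey(res$dnsnp$chrom, res$dnsnp$pos))
    dd <- res$polarized$derivedDosage
    sfsRows <- list(); res$sfs <- list()
    for (g in names(groups)) {
      for (cl in names(classSites)) {
        rows <- which(resolved & classSites[[cl]])
        sub <- dd[rows, groups[[g]], drop = FALSE]
        derived <- rowSums(sub, na.rm = TRUE)
        called <- 2L * rowSums(!is.na(sub))
        sfs <- computeSFS(derived, called, config$projectionN,
                          siteClass = cl, group = g)
        res$sfs[[paste(g, cl, sep = ".")]] <- sfs
        sfsRows[[paste(g, cl)]] <- data.frame(
          group = g, class = cl, derivedCount = sfs$derivedCount,
          nSites = sfs$nSites, stringsAsFactors = FALSE)
      }
    }
    res$sfsTable <- do.call(rbind, sfsRows)
    rownames(res$sfsTable) <- NULL
    outputs["sfs"] <- writeTsv(res$sfsTable,
                               file.path(config$outdir, "sfs.tsv"))
    rf <- lapply(names(res$sfs), function(k)
      data.frame(key = k,
                 rareFraction = rareFraction(res$sfs[[k]],
                                             config$dafThreshold)))
    res$rare <- do.call(rbind, rf)
    outputs["rare_fractions"] <- writeTsv(
      res$rare, file.path(config$outdir, "rare_fractions.tsv"))
  }

  if (st("roh")) {
    segs <- rohScan(ds, config$roh)
    genomeLen <- if (!is.null(chromLengths)) sum(chromLengths) else
      sum(tapply(ds@pos, ds@chrom, max))
    res$rohSegments <- segs
    res$rohSummary <- rohSummary(segs, cladeMap, genomeLen)
    outputs["roh_segments"] <- writeTsv(
      segs, file.path(config$outdir, "roh_segments.tsv"))
    outputs["roh_by_clade"] <- writeTsv(
      res$rohSummary, file.path(config$outdir, "roh_by_clade.tsv"))
  }

  if (st("load")) {
    keys <- siteKey(ds@chrom, ds@pos)
    ffInDs <- res$fourfold[siteKey(res$fourfold$chrom, res$fourfold$pos)
                           %in% keys, , drop = FALSE]
    res$load <- loadTable(res$polarized$derivedDosage, keys, res$dnsnp,
                          ffInDs, status = res$polarized$sites$status)
    res$cladeLoad <- cladeLoadTable(res$load, cladeMap)
    outputs["load_by_sample"] <- writeTsv(
      res$load, file.path(config$outdir, "load_by_sample.tsv"))
    outputs["load_by_clade"] <- writeTsv(
      res$cladeLoad$clades, file.path(config$outdir, "load_by_clade.tsv"))
    outputs["load_tests"] <- writeTsv(
      res$cladeLoad$tests, file.path(config$outdir, "load_tests.tsv"))
    pis <- setNames(res$pis$medianPis, res$pis$group)
    loads <- setNames(res$cladeLoad$clades$median,
                      res$cladeLoad$clades$clade)
    common <- intersect(names(pis), names(loads))
    if (length(common) >= 3) {
      res$pisLoad <- pisLoadRelation(pis[common], loads[common])
      outputs["pis_load_relation"] <- writeTsv(
        res$pisLoad, file.path(config$outdir, "pis_load_relation.tsv"))
    }
  }

  if (st("sweeps") && !is.null(config$track2) && !is.null(res$fst)) {
    track2 <- readWindowScores(config$track2)
    outA <- topQuantileWindows(res$fst, config$sweepQ)
    outB <- topQuantileWindows(track2, config$sweepQ)
    genes <- res$annotation$spans
    geneTab <- data.frame(geneId = genes$geneId, chrom = genes$chrom,
                          start = genes$start, end = genes$end,
                          stringsAsFactors = FALSE)
    res$candidates <- intersectAndMap(outA, outB, geneTab,
                                      comparison = "fst-vs-track2")
    outputs["sweep_candidates"] <- writeTsv(
      data.frame(comparison = rep(res$candidates$comparison,
                                  length(res$candidates$genes)),
                 gene = res$candidates$genes),
      file.path(config$outdir, "sweep_candidates.tsv"))
  }

  manifest <- list(
    package = "purgescan",
    version = as.character(utils::packageVersion("purgescan")),
    stages = config$stages,
    parameters = config[setdiff(names(config),
                                c("vcf", "fasta", "gff", "outgroups",
                                  "clades", "dnsnp", "track2", "outdir",
                                  "roh"))],
    inputs = {
      ins <- unlist(Filter(Negate(is.null),
        config[c("vcf", "fasta", "gff", "outgroups", "clades", "dnsnp",
                 "track2")]))
      setNames(as.list(unname(tools::md5sum(ins))), basename(ins))
    },
    outputs = setNames(as.list(unname(tools::md5sum(unname(outputs)))),
                       basename(unname(outputs))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  summaryLines <- c(
    "purgescan pipeline summary",
    sprintf("sites after filtering: %d; samples: %d",
            nSites(ds), nSamples(ds)),
    if (!is.null(res$filterCounts))
      sprintf("filter removals: %s",
              paste(names(res$filterCounts), res$filterCounts,
                    sep = "=", collapse = ", ")),
    if (!is.null(res$pis))
      sprintf("median pi_s by group: %s",
              paste(res$pis$group, signif(res$pis$medianPis, 4),
                    sep = "=", collapse = ", ")),
    if (!is.null(res$cladeLoad))
      sprintf("median load by clade: %s",
              paste(res$cladeLoad$clades$clade,
                    signif(res$cladeLoad$clades$median, 4),
                    sep = "=", collapse = ", ")),
    if (!is.null(res$rohSummary))
      sprintf("mean ROH kb/sample by clade: %s",
              paste(res$rohSummary$clade,
                    signif(res$rohSummary$meanTotalKbPerSample, 4),
                    sep = "=", collapse = ", ")),
    if (!is.null(res$candidates))
      sprintf("sweep candidate genes: %d", length(res$candidates$genes)))
  writeLines(summaryLines, file.path(config$outdir, "summary.txt"))
  invisible(res)
}
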