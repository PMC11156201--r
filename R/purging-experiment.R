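#' Purging experiment: recessive vs additive deleterious variation under a
#' highland bottleneck-and-selfing scenario
#'
#' For each replicate, simulates the [highlandLowlandScenario()] twice —
#' once with fully recessive deleterious mutations (h = 0) and once with
#' additive ones (h = 0.5) — writes the bundle, runs the full pipeline
#' (import, annotate, polarize, stats, roh, load) and tabulates per-clade
#' median load, four-fold diversity, ROH totals and rare-variant fractions,
#' together with per-replicate directional indicators.  Under recessivity,
#' inbreeding exposes deleterious alleles as homozygotes and selection
#' purges them, so highland (bottlenecked, selfing) clades are expected to
#' show lower load, an excess of rare deleterious variants, more ROH and
#' lower pi_s than the lowland clade; with h = 0.5 the load ordering is not
#' expected to be enforced.
#'
#' The variant filter runs with MAF 0 here: the experiment's rare-variant
#' and load signals live in the low-frequency tail that a 0.05 MAF cut
#' would delete at these sample sizes.
#'
#' @param scale scenario scale, `"small"` or `"default"`.
#' @param nReplicates replicates per arm.
#' @param seed master seed; every replicate/arm seed derives from it.
#' @param keepBundles keep the per-replicate bundle directories (default:
#'   simulate into a temporary directory and delete).
#' @return data.frame with one row per (replicate, arm): per-clade medians,
#'   group metrics, and logical direction indicators
#'   (loadHighlandLower, pisHighlandLower, rohHighlandGreater,
#'   rareDnsnpHighlandGreater, pisLoadSpearmanPositive).  The
#'   `"signTests"` attribute holds one-sided binomial sign tests of each
#'   indicator within each arm.
#' @export
purgingExperiment <- function(scale = c("small", "default"),
                              nReplicates = 30L, seed = 1L,
                              keepBundles = FALSE) {
  scale <- match.arg(scale)
  arms <- c(h0 = 0, h05 = 0.5)
  rows <- list()
  for (rep in seq_len(nReplicates)) {
    for (a in names(arms)) {
      cfg <- highlandLowlandScenario(scale, hDel = arms[[a]],
                                     seed = deriveSeed(seed, "rep", rep, a))
      sim <- simulatePopulations(cfg)
      dir <- if (keepBundles)
        file.path(tempdir(), sprintf("purging_%s_rep%02d", a, rep))
      else tempfile("purging_")
      writeBundle(sim, dir)
      pcfg <- bundleConfig(
        dir, outdir = file.path(dir, "out"),
        stages = c("import", "annotate", "polarize", "stats", "roh", "load"),
        filter = list(minCalled = 0.8, minMaf = 0, minDepth = 0))
      res <- suppressWarnings(runPipeline(pcfg))
      rows[[paste(rep, a)]] <- summarizeReplicate(res, sim$cladeMap, rep, a)
      if (!keepBundles) unlink(dir, recursive = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "signTests") <- signTests(out)
  out
}

summarizeReplicate <- function(res, cladeMap, rep, arm) {
  highClades <- unique(cladeMap$clade[cladeMap$altitude == "high"])
  lowClades <- unique(cladeMap$clade[cladeMap$altitude == "low"])
  loads <- setNames(res$cladeLoad$clades$median, res$cladeLoad$clades$clade)
  pis <- setNames(res$pis$medianPis, res$pis$group)
  rohSam <- attr(res$rohSummary, "samples")
  rohBy <- tapply(rohSam$totalKb,
                  cladeMap$altitude[match(rohSam$sample, cladeMap$sample)],
                  mean)
  gv <- function(x, k, default = NA_real_) {
    v <- unname(x[k])
    if (length(v) == 0 || is.na(v)) default else v
  }
  rare <- setNames(res$rare$rareFraction, res$rare$key)
  sp <- if (!is.null(res$pisLoad)) res$pisLoad$spearman else NA_real_
  data.frame(
    replicate = rep, arm = arm,
    loadLowland = unname(median(loads[lowClades], na.rm = TRUE)),
    loadHighland = unname(median(loads[highClades], na.rm = TRUE)),
    pisLowland = unname(median(pis[lowClades], na.rm = TRUE)),
    pisHighland = unname(median(pis[highClades], na.rm = TRUE)),
    rohLowKbPerSample = gv(rohBy, "low", 0),
    rohHighKbPerSample = gv(rohBy, "high", 0),
    rareDnsnpLow = gv(rare, "low.dnsnp"),
    rareDnsnpHigh = gv(rare, "high.dnsnp"),
    rareFourfoldLow = gv(rare, "low.fourfold"),
    rareFourfoldHigh = gv(rare, "high.fourfold"),
    pisLoadSpearman = sp,
    loadHighlandLower = unname(median(loads[highClades], na.rm = TRUE) <
                                 median(loads[lowClades], na.rm = TRUE)),
    pisHighlandLower = unname(median(pis[highClades], na.rm = TRUE) <
                                median(pis[lowClades], na.rm = TRUE)),
    rohHighlandGreater = gv(rohBy, "high", 0) > gv(rohBy, "low", 0),
    rareDnsnpHighlandGreater = gv(rare, "high.dnsnp") > gv(rare, "low.dnsnp"),
    pisLoadSpearmanPositive = !is.na(sp) && sp > 0,
    stringsAsFactors = FALSE)
}

## One-sided sign test per direction indicator within each arm.
signTests <- function(tab) {
  inds <- c("loadHighlandLower", "pisHighlandLower", "rohHighlandGreater",
            "rareDnsnpHighlandGreater", "pisLoadSpearmanPositive")
  out <- list()
  for (a in unique(tab$arm)) {
    sub <- tab[tab$arm == a, ]
    for (ind in inds) {
      v <- sub[[ind]]
      v <- v[!is.na(v)]
      out[[paste(a, ind, sep = ".")]] <- data.frame(
        arm = a, indicator = ind, successes = sum(v), n = length(v),
        p = if (length(v)) binom.test(sum(v), length(v),
                                      alternative = "greater")$p.value
            else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
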