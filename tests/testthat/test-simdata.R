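smallNeutralConfig <- function(seed, N = 60L, gens = 200L, L = 20000L,
                               mu = 2e-5, nSample = 10L, selfing = 0) {
  simulationConfig(
    seed = seed, nGenerations = gens,
    populations = list(populationPlan("p1", N, selfing = selfing,
                                      nGenerations = gens)),
    genomeSpec = list(type = "neutral", chromLengths = c(chr1 = L)),
    muNeutral = mu, sampleSizes = c(p1 = nSample))
}

test_that("scenario configurations are valid and honor their contracts", {
  for (scale in c("small", "default")) {
    cfg <- highlandLowlandScenario(scale)
    expect_true(validObject(cfg))
    pops <- cfg@populations
    names(pops) <- vapply(pops, function(p) p$name, "")
    # highland populations split, bottleneck and self at >= 0.5
    high <- pops[vapply(pops, function(p) p$altitude == "high", TRUE)]
    expect_gte(length(high), 2L)
    lowN <- pops$lowland$epochs$N[1]
    for (p in high) {
      expect_false(is.na(p$parent))
      expect_lt(max(p$epochs$N), lowN)
      expect_gte(p$selfing, 0.5)
    }
    expect_equal(cfg@hDel, 0)
    # desk scale: total diploid genotype-generations within budget
    gg <- sum(vapply(pops, function(p)
      sum((p$epochs$end - p$epochs$start) * p$epochs$N), 0))
    if (scale == "small") expect_lte(gg, 1e8)
  }

  # invalid configurations are rejected
  expect_error(simulationConfig(muNeutral = 1.5), "rates")
  expect_error(simulationConfig(populations = list(
    populationPlan("p1", 1L, nGenerations = 100L))), "N must be")
  badEpochs <- data.frame(start = c(0L, 60L), end = c(50L, 100L),
                          N = c(10L, 10L))
  expect_error(simulationConfig(populations = list(
    populationPlan("p1", badEpochs, nGenerations = 100L))), "tile")
})

test_that("identical config and seed reproduce bit-identical bundles", {
  cfg <- smallNeutralConfig(99L)
  d1 <- tempfile(); d2 <- tempfile()
  writeBundle(simulatePopulations(cfg), d1)
  writeBundle(simulatePopulations(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("an all-lethal planted configuration reports extinction with its
           generation", {
  cfg <- smallNeutralConfig(5L, N = 20L, gens = 30L)
  cfg@planted <- data.frame(pop = "p1", gen = 10L, chrom = "chr1",
                            targetPos = 10000L, s = 1, h = 1, copies = 20L)
  expect_error(simulatePopulations(cfg), "extinct.*generation 10")
})

test_that("bundles round-trip through the VCF reader", {
  cfg <- smallNeutralConfig(13L)
  sim <- simulatePopulations(cfg)
  dir <- tempfile()
  writeBundle(sim, dir)
  back <- suppressMessages(readVCF(file.path(dir, "variants.vcf")))
  expect_equal(dosages(back), dosages(sim$dataset))
  expect_equal(siteInfo(back), siteInfo(sim$dataset))
  # clade map and outgroup tables parse
  cm <- readCladeMap(file.path(dir, "clades.tsv"))
  expect_equal(nrow(cm), 10L)
  og <- readOutgroupTable(file.path(dir, "outgroups.tsv"))
  expect_equal(nrow(og), nSites(sim$dataset))
})

test_that("a mutation-free simulation writes a valid header-only VCF", {
  cfg <- smallNeutralConfig(3L, gens = 20L, mu = 0)
  sim <- simulatePopulations(cfg)
  expect_equal(nSites(sim$dataset), 0L)
  dir <- tempfile()
  writeBundle(sim, dir)
  ds <- suppressWarnings(readVCF(file.path(dir, "variants.vcf")))
  expect_equal(nSites(ds), 0L)
})

test_that("emitted site classes are literally true under annotation of the
           emitted reference", {
  cfg <- simulationConfig(
    seed = 41L, nGenerations = 150L,
    populations = list(populationPlan("p1", 50L, nGenerations = 150L)),
    genomeSpec = list(type = "genic", chromLengths = c(chr1 = 30000L),
                      codonsPerGene = 80L, intronBp = 120L, spacerBp = 200L),
    muNeutral = 4e-5, muDel = 6e-6, muLof = 6e-6, sDel = 0.05, hDel = 0.2,
    sLof = 0.3, hLof = 0.1, sampleSizes = c(p1 = 12L))
  sim <- simulatePopulations(cfg)
  dir <- tempfile()
  writeBundle(sim, dir)
  ann <- loadAnnotation(file.path(dir, "reference.fa"),
                        file.path(dir, "annotation.gff3"))
  tr <- sim$truth
  expect_gt(nrow(tr), 50)
  expect_gt(sum(tr$class == "stopgain"), 0)
  eff <- purgescan:::variantEffects(ann, tr$chrom, tr$pos, tr$ancestral,
                                    tr$derived)
  expect_true(all(eff[tr$class == "stopgain"] == "stopgain"))
  expect_true(all(eff[tr$class == "deleterious"] == "nonsynonymous"))
  expect_true(all(eff[tr$class == "neutral"] == "synonymous"))
  # neutral truth sites are four-fold degenerate in the annotation
  ff <- fourfoldSites(ann)
  neuKeys <- paste(tr$chrom, tr$pos)[tr$class == "neutral"]
  expect_true(all(neuKeys %in% paste(ff$chrom, ff$pos)))
})

test_that("selfing depresses heterozygosity by the equilibrium
           inbreeding coefficient", {
  F <- 0.6
  cfg <- smallNeutralConfig(61L, N = 200L, gens = 600L, L = 40000L,
                            mu = 1e-5, nSample = 40L, selfing = F)
  sim <- simulatePopulations(cfg)
  d <- dosages(sim$dataset)
  p <- rowMeans(d) / 2
  hetObs <- rowMeans(d == 1L)
  keep <- p > 0.05 & p < 0.95
  ratio <- sum(hetObs[keep]) / sum(2 * p[keep] * (1 - p[keep]))
  fis <- F / (2 - F)
  expect_lt(abs(ratio - (1 - fis)), 0.12)
})

test_that("recessive load is purged under bottleneck plus selfing but not
           under additivity", {
  reps <- 8L
  lowWins <- c(h0 = 0L, h05 = 0L)
  for (r in seq_len(reps)) {
    for (arm in c("h0", "h05")) {
      cfg <- highlandLowlandScenario("small",
                                     hDel = if (arm == "h0") 0 else 0.5,
                                     seed = deriveSeed(400L, r, arm))
      sim <- simulatePopulations(cfg)
      tr <- sim$truth
      del <- tr$class == "deleterious"
      highMean <- mean(c(tr$freq_highA[del], tr$freq_highB[del],
                         tr$freq_highC[del], tr$freq_highD[del]))
      lowWins[arm] <- lowWins[arm] + (highMean < mean(tr$freq_lowland[del]))
    }
  }
  # recessive arm: purging drives highland deleterious frequencies down in
  # (nearly) every replicate; the additive arm gets no such guarantee
  expect_gte(lowWins[["h0"]], reps - 1L)
})

test_that("block mode runs and keeps the non-recombining haplotype
           structure plausible", {
  cfg <- smallNeutralConfig(77L, N = 40L, gens = 100L, L = 10000L,
                            mu = 1e-5)
  cfg@mode <- "block"
  sim <- simulatePopulations(cfg)
  expect_s4_class(sim$dataset, "GenotypeDataset")
  expect_true(all(dosages(sim$dataset) %in% 0:2))
})
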