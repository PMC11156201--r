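#' Describe one population's demographic plan
#'
#' @param name population name (also the clade label downstream).
#' @param N diploid size, either a scalar (constant) or a data.frame with
#'   columns start/end/N tiling the population's lifetime in generations.
#' @param selfing probability that an offspring is produced by selfing.
#' @param parent name of the parent population, or `NA` for the root.
#' @param splitGen generation at which the population is founded from its
#'   parent (0 for the root).
#' @param altitude habitat label carried into the clade map ("high"/"low").
#' @param nGenerations total scenario length; needed to expand a scalar `N`.
#' @return a population plan list for [simulationConfig()].
#' @export
populationPlan <- function(name, N, selfing = 0, parent = NA_character_,
                           splitGen = 0L, altitude = "low",
                           nGenerations = NULL) {
  if (!is.data.frame(N)) {
    stopifnot(!is.null(nGenerations))
    N <- data.frame(start = as.integer(splitGen),
                    end = as.integer(nGenerations), N = as.integer(N))
  }
  list(name = name, parent = parent, splitGen = as.integer(splitGen),
       epochs = N, selfing = selfing, altitude = altitude)
}

#' Construct a simulation scenario configuration
#'
#' See [SimulationConfig-class] for the meaning of each field.  Defaults give
#' a single constant population with neutral variation only.
#'
#' @param seed master seed (determinism contract: identical config + seed
#'   reproduce bit-identical output bundles).
#' @param nGenerations generations to simulate.
#' @param populations list of [populationPlan()] objects.
#' @param genomeSpec toy genome specification (see [buildToyGenome()]).
#' @param muNeutral,muDel,muLof per-candidate-site per-generation mutation
#'   rates of the three site classes.
#' @param sDel,hDel selection/dominance of the deleterious missense-like
#'   class; `hDel = 0` makes it fully recessive.
#' @param sLof,hLof selection/dominance of the stopgain class (defaults:
#'   nearly recessive, strongly deleterious).
#' @param outgroupDivergence expected substitutions/site per outgroup lineage.
#' @param sampleSizes named vector of diploids sampled per population at the
#'   final generation.
#' @param mode `"independent"` sites (free recombination; closed-form checks
#'   exact) or a single non-recombining `"block"`.
#' @param planted data.frame of planted mutations (pop, gen, chrom,
#'   targetPos, s, h, copies); `s < 0` plants a beneficial allele.
#' @return a validated [SimulationConfig-class] object.
#' @export
simulationConfig <- function(seed = 1L,
                             nGenerations = 100L,
                             populations = list(
                               populationPlan("pop1", 100L,
                                              nGenerations = nGenerations)),
                             genomeSpec = list(type = "neutral",
                                               chromLengths = c(chr1 = 10000L)),
                             muNeutral = 1e-5, muDel = 0, muLof = 0,
                             sDel = 0.1, hDel = 0, sLof = 0.9, hLof = 0.02,
                             outgroupDivergence = 0.01,
                             sampleSizes = NULL, mode = "independent",
                             planted = NULL) {
  popNames <- vapply(populations, function(p) p$name, "")
  if (is.null(sampleSizes)) {
    sampleSizes <- setNames(rep(10L, length(populations)), popNames)
  }
  if (is.null(planted)) {
    planted <- data.frame(pop = character(), gen = integer(),
                          chrom = character(), targetPos = integer(),
                          s = numeric(), h = numeric(), copies = integer(),
                          stringsAsFactors = FALSE)
  }
  new("SimulationConfig", seed = as.integer(seed),
      nGenerations = as.integer(nGenerations), populations = populations,
      muNeutral = muNeutral, muDel = muDel, muLof = muLof,
      sDel = sDel, hDel = hDel, sLof = sLof, hLof = hLof,
      outgroupDivergence = outgroupDivergence,
      sampleSizes = setNames(as.integer(sampleSizes), names(sampleSizes)),
      mode = mode, genomeSpec = genomeSpec, planted = planted)
}

popSizeAt <- function(plan, gen) {
  ep <- plan$epochs
  i <- which(gen > ep$start & gen <= ep$end)
  if (length(i) != 1) stop("no epoch covers generation ", gen,
                           " for population ", plan$name)
  ep$N[i]
}

#' Run a forward-time Wright-Fisher simulation
#'
#' Per-generation cycle: mutation (Poisson influx over the candidate-site
#' pools; a mutation hitting an already-segregating site adds a copy of the
#' same derived allele, keeping sites biallelic), viability selection with
#' multiplicative fitness 1 / 1-hs / 1-s per site, then mating with
#' probability `selfing` of self-fertilization.  Populations split at their
#' configured generations by sampling founders from the parent.  The random
#' stream is keyed per population and generation from the master seed.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `dataset` (a [GenotypeDataset-class] of sites
#'   segregating in the final sample), `truth` (per-site ground truth:
#'   ancestral/derived allele, class, s, h, outgroup alleles, per-population
#'   final frequencies), `genome` (the toy genome), and `cladeMap`
#'   (sample-to-population table with altitude labels).
#' @export
simulatePopulations <- function(config) {
  validObject(config)
  seed <- config@seed
  mode <- config@mode
  genome <- buildToyGenome(config@genomeSpec, seed)
  cand <- genome$candidates
  pools <- split(seq_len(nrow(cand)), cand$class)
  altList <- strsplit(cand$alts, ",", fixed = TRUE)
  mu <- c(neutral = config@muNeutral, deleterious = config@muDel,
          stopgain = config@muLof)
  sClass <- c(neutral = 0, deleterious = config@sDel, stopgain = config@sLof)
  hClass <- c(neutral = 0, deleterious = config@hDel, stopgain = config@hLof)

  plans <- config@populations
  names(plans) <- vapply(plans, function(p) p$name, "")
  nGen <- config@nGenerations
  gcol <- if (mode == "block") 2L else 1L  # matrix columns per individual

  ## active-site registry; genotype matrices are sites x (gcol * N)
  active <- integer(0)
  derived <- character(0)
  sVec <- numeric(0); hVec <- numeric(0)
  cand2row <- integer(nrow(cand))  # 0 inactive, -1 retired (fixed), else row
  plantedInfo <- list()
  pops <- list()
  compactEvery <- 8L

  for (p in plans) if (is.na(p$parent)) {
    pops[[p$name]] <- matrix(0L, 0L, gcol * popSizeAt(p, 1L))
  }

  for (gen in seq_len(nGen)) {
    ## founding: child populations sample founders from the parent
    for (p in plans) {
      if (!is.na(p$parent) && p$splitGen == gen - 1L) {
        parentG <- pops[[p$parent]]
        Nf <- popSizeAt(p, gen)
        set.seed(deriveSeed(seed, "split", gen, p$name))
        nPar <- ncol(parentG) / gcol
        founders <- sample.int(nPar, Nf, replace = Nf > nPar)
        colIdx <- rep(gcol * (founders - 1L), each = gcol) + seq_len(gcol)
        pops[[p$name]] <- parentG[, colIdx, drop = FALSE]
      }
    }
    alive <- names(plans)[!vapply(plans, function(p)
      is.null(pops[[p$name]]), TRUE)]

    ## --- phase A: mutation events for every population ------------------
    ## new activations are global (every population gains the row); copy
    ## increments stay local to the mutated population
    newIds <- integer(0); newDer <- character(0)
    newS <- numeric(0); newH <- numeric(0)
    newPop <- character(0); newCols <- list()
    incr <- setNames(vector("list", length(alive)), alive)
    for (pn in alive) {
      pidx <- match(pn, names(plans))
      p <- plans[[pn]]
      set.seed(deriveSeed(seed, "mut", gen, pidx))
      G <- pops[[pn]]
      N <- ncol(G) / gcol
      rows <- integer(0); cols <- integer(0)
      for (cls in names(mu)) {
        pool <- pools[[cls]]
        if (is.null(pool) || mu[[cls]] <= 0) next
        k <- rpois(1L, 2 * N * length(pool) * mu[[cls]])
        if (k == 0) next
        ids <- pool[sample.int(length(pool), k, replace = TRUE)]
        for (id in ids) {
          r <- cand2row[id]
          j <- sample.int(N, 1L)
          col <- if (mode == "block") 2L * (j - 1L) + sample.int(2L, 1L)
                 else j
          if (r == -1L) next
          if (r == 0L) {
            newIds <- c(newIds, id)
            alts <- altList[[id]]
            newDer <- c(newDer, if (length(alts) == 1L) alts else
              alts[sample.int(length(alts), 1L)])
            newS <- c(newS, unname(sClass[cls]))
            newH <- c(newH, unname(hClass[cls]))
            newPop <- c(newPop, pn)
            newCols[[length(newIds)]] <- col
            cand2row[id] <- length(active) + length(newIds)
          } else if (r <= length(active)) {
            rows <- c(rows, r - 1L); cols <- c(cols, col - 1L)
          }  # else: activated earlier this generation; skip the rare rehit
        }
      }
      ## planted mutations
      pl <- if (nrow(config@planted) == 0L) config@planted else
        config@planted[config@planted$pop == pn & config@planted$gen == gen, ,
                       drop = FALSE]
      for (m in seq_len(nrow(pl))) {
        free <- pools$neutral[cand2row[pools$neutral] == 0L &
                              cand$chrom[pools$neutral] == pl$chrom[m]]
        if (!length(free)) stop("no free candidate site to plant at")
        id <- free[which.min(abs(cand$pos[free] - pl$targetPos[m]))]
        carriers <- sample.int(N, min(pl$copies[m], N))
        ccols <- if (mode == "block") 2L * (carriers - 1L) + 1L else carriers
        newIds <- c(newIds, id)
        newDer <- c(newDer, altList[[id]][1L])
        newS <- c(newS, pl$s[m]); newH <- c(newH, pl$h[m])
        newPop <- c(newPop, pn)
        newCols[[length(newIds)]] <- ccols
        cand2row[id] <- length(active) + length(newIds)
        plantedInfo[[length(plantedInfo) + 1L]] <-
          data.frame(chrom = cand$chrom[id], pos = cand$pos[id],
                     geneId = cand$geneId[id], pop = pn,
                     stringsAsFactors = FALSE)
      }
      incr[[pn]] <- list(rows = rows, cols = cols)
    }

    ## --- phase B: selection + reproduction per population ---------------
    K <- length(newIds)
    sAll <- c(sVec, newS); hAll <- c(hVec, newH)
    for (pn in alive) {
      pidx <- match(pn, names(plans))
      p <- plans[[pn]]
      set.seed(deriveSeed(seed, "mate", gen, pidx))
      G <- pops[[pn]]
      extra <- matrix(0L, K, ncol(G))
      if (K > 0) {
        mine <- which(newPop == pn)
        for (m in mine) extra[m, newCols[[m]]] <- 1L
      }
      Nnext <- popSizeAt(p, gen)
      out <- if (mode == "block") {
        wf_next_generation_block(G, extra, incr[[pn]]$rows, incr[[pn]]$cols,
                                 sAll, hAll, p$selfing, Nnext)
      } else {
        wf_next_generation(G, extra, incr[[pn]]$rows, incr[[pn]]$cols,
                           sAll, hAll, p$selfing, Nnext)
      }
      if (nrow(out) == 0L && length(sAll) > 0L) {
        stop(sprintf(
          "population '%s' went extinct (all fitness zero) at generation %d",
          pn, gen))
      }
      if (length(sAll) == 0L) out <- matrix(0L, 0L, gcol * Nnext)
      pops[[pn]] <- out
    }
    active <- c(active, newIds)
    derived <- c(derived, newDer)
    sVec <- sAll; hVec <- hAll

    ## --- periodic compaction: drop globally lost / fixed sites ----------
    if (length(active) && (gen %% compactEvery == 0L || gen == nGen)) {
      tot <- Reduce(`+`, lapply(pops, rowSums))
      cap <- sum(vapply(pops, ncol, 0L)) * (2L / gcol)
      lost <- tot == 0
      fixed <- tot == cap
      if (any(lost) || any(fixed)) {
        cand2row[active[lost]] <- 0L
        cand2row[active[fixed]] <- -1L
        keep <- !(lost | fixed)
        active <- active[keep]; derived <- derived[keep]
        sVec <- sVec[keep]; hVec <- hVec[keep]
        cand2row[active] <- seq_along(active)
        pops <- lapply(pops, function(g) g[keep, , drop = FALSE])
      }
    }
  }

  ## --- final sampling ---
  set.seed(deriveSeed(seed, "finalsample"))
  sampleSizes <- config@sampleSizes
  dosageCols <- list(); sampleNames <- character(0); cladeRows <- list()
  for (pn in names(sampleSizes)) {
    G <- pops[[pn]]
    N <- ncol(G) / gcol
    k <- sampleSizes[[pn]]
    take <- sample.int(N, k, replace = k > N)
    d <- if (mode == "block") {
      G[, 2L * (take - 1L) + 1L, drop = FALSE] + G[, 2L * take, drop = FALSE]
    } else G[, take, drop = FALSE]
    dosageCols[[pn]] <- d
    ids <- sprintf("%s_%02d", pn, seq_len(k))
    sampleNames <- c(sampleNames, ids)
    cladeRows[[pn]] <- data.frame(sample = ids, clade = pn,
                                  altitude = plans[[pn]]$altitude,
                                  stringsAsFactors = FALSE)
  }
  dosage <- do.call(cbind, dosageCols)
  colnames(dosage) <- sampleNames
  seg <- if (length(active)) {
    tot <- rowSums(dosage)
    tot > 0 & tot < 2L * ncol(dosage)
  } else logical(0)

  idx <- which(seg)
  ids <- active[idx]
  chromSeq <- lapply(seq_along(genome$seqs), function(i)
    strsplit(as.character(genome$seqs[[i]]), "")[[1]])
  names(chromSeq) <- names(genome$seqs)
  anc <- vapply(seq_along(ids), function(m)
    chromSeq[[cand$chrom[ids[m]]]][cand$pos[ids[m]]], "")
  ## outgroup alleles: the true ancestral base mutated independently per
  ## lineage with probability 1 - exp(-d); outgroups are never polymorphic.
  set.seed(deriveSeed(seed, "outgroup"))
  pmut <- 1 - exp(-config@outgroupDivergence)
  ogDraw <- function(a) {
    hit <- runif(length(a)) < pmut
    out <- a
    if (any(hit)) out[hit] <- vapply(a[hit], function(b)
      sample(setdiff(BASES, b), 1L), "")
    out
  }
  og1 <- ogDraw(anc); og2 <- ogDraw(anc)

  popFreq <- vapply(names(plans), function(pn) {
    G <- pops[[pn]]
    (rowSums(G) / (2 * ncol(G) / gcol))[idx]
  }, numeric(length(idx)))
  if (length(idx) == 1L) popFreq <- matrix(popFreq, nrow = 1,
                                           dimnames = list(NULL, names(plans)))

  truth <- data.frame(chrom = cand$chrom[ids], pos = cand$pos[ids],
                      ancestral = anc, derived = derived[idx],
                      class = cand$class[ids], s = sVec[idx], h = hVec[idx],
                      og1 = og1, og2 = og2, geneId = cand$geneId[ids],
                      stringsAsFactors = FALSE)
  if (length(idx)) {
    colnames(popFreq) <- paste0("freq_", names(plans))
    truth <- cbind(truth, as.data.frame(popFreq))
  }
  o <- siteOrder(truth$chrom, truth$pos)
  truth <- truth[o, , drop = FALSE]
  rownames(truth) <- NULL

  ds <- GenotypeDataset(dosage[idx, , drop = FALSE][o, , drop = FALSE],
                        chrom = truth$chrom, pos = truth$pos,
                        ref = truth$ancestral, alt = truth$derived)
  cladeMap <- do.call(rbind, cladeRows)
  rownames(cladeMap) <- NULL
  attr(truth, "planted") <- if (length(plantedInfo))
    do.call(rbind, plantedInfo) else NULL
  list(dataset = ds, truth = truth, genome = genome, cladeMap = cladeMap,
       config = config)
}

#' Preset highland/lowland purging scenario
#'
#' One large, constant, outcrossing "lowland" population plus four
#' "highland" populations that split from it simultaneously, bottleneck to
#' graded small sizes and reproduce with selfing rate 0.8.  The deleterious
#' missense-like class is recessive (`hDel = 0`) by default; pass
#' `hDel = 0.5` for the additive contrast arm.
#'
#' @param scale `"small"` (desk scale) or `"default"` (larger sizes and a
#'   longer run).
#' @param hDel dominance of the deleterious class.
#' @param seed master seed stored in the config.
#' @return a [SimulationConfig-class].
#' @export
highlandLowlandScenario <- function(scale = c("small", "default"), hDel = 0,
                                    seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "small") {
    nGen <- 700L; split <- 500L
    lowN <- 120L; highN <- c(25L, 40L, 60L, 90L)
    genomeSpec <- list(type = "genic",
                       chromLengths = c(chr1 = 120000L, chr2 = 80000L),
                       codonsPerGene = 120L, intronBp = 150L, spacerBp = 250L)
    sizes <- c(lowland = 24L, highA = 12L, highB = 12L, highC = 12L,
               highD = 12L)
  } else {
    nGen <- 2000L; split <- 1400L
    lowN <- 400L; highN <- c(60L, 80L, 100L, 120L)
    genomeSpec <- list(type = "genic",
                       chromLengths = c(chr1 = 300000L, chr2 = 200000L),
                       codonsPerGene = 120L, intronBp = 150L, spacerBp = 250L)
    sizes <- c(lowland = 40L, highA = 20L, highB = 20L, highC = 20L,
               highD = 20L)
  }
  highNames <- c("highA", "highB", "highC", "highD")
  pops <- c(
    list(populationPlan("lowland", lowN, selfing = 0, altitude = "low",
                        nGenerations = nGen)),
    lapply(seq_along(highNames), function(i)
      populationPlan(highNames[i], highN[i], selfing = 0.8,
                     parent = "lowland", splitGen = split, altitude = "high",
                     nGenerations = nGen)))
  simulationConfig(
    seed = seed, nGenerations = nGen, populations = pops,
    genomeSpec = genomeSpec,
    muNeutral = 1.4e-5, muDel = 1.2e-6, muLof = 8e-7,
    sDel = 0.1, hDel = hDel, sLof = 0.9, hLof = 0.02,
    outgroupDivergence = 0.01, sampleSizes = sizes)
}
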