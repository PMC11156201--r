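test_that("the load proxy is the ratio of derived dosage sums", {
  # sample A: het at one dnSNP (1) + hom-derived at another (2) = 3 derived
  # deleterious alleles; 30 derived four-fold alleles -> load 0.1
  dn <- data.frame(chrom = "chr1", pos = c(100L, 200L))
  ff <- data.frame(chrom = "chr1", pos = 300L + seq_len(15L) * 10L)
  keys <- paste("chr1", c(dn$pos, ff$pos), sep = ":")
  dd <- rbind(c(1L, 0L), c(2L, 0L),
              matrix(2L, 15, 2))
  colnames(dd) <- c("A", "B")
  tab <- loadTable(dd, keys, dn, ff)
  expect_equal(tab$load[tab$sample == "A"], 3 / 30)
  expect_equal(tab$dnsnpAlleles[tab$sample == "A"], 3L)
  # zero derived deleterious alleles give load 0
  expect_equal(tab$load[tab$sample == "B"], 0)

  # missing calls drop out of both sums
  dd2 <- dd; dd2[3, "A"] <- NA
  tab2 <- loadTable(dd2, keys, dn, ff)
  expect_equal(tab2$load[tab2$sample == "A"], 3 / 28)

  # zero denominator is flagged, not divided
  tab3 <- loadTable(dd[1:2, , drop = FALSE], keys[1:2], dn, ff)
  expect_true(all(tab3$undefined))
  expect_true(all(is.na(tab3$load)))

  # overlapping site lists are refused
  expect_error(loadTable(dd, keys, dn, rbind(ff, dn[1, ])), "disjoint")
})

test_that("the proxy ignores monomorphic padding and is scale invariant", {
  dn <- data.frame(chrom = "chr1", pos = 100L)
  ff <- data.frame(chrom = "chr1", pos = c(200L, 250L))
  keys <- c("chr1:100", "chr1:200", "chr1:250")
  dd <- rbind(c(1L, 2L), c(2L, 1L), c(1L, 1L))
  colnames(dd) <- c("A", "B")
  base <- loadTable(dd, keys, dn, ff)

  # monomorphic extra sites (dosage 0 everywhere) change nothing
  keysPad <- c(keys, "chr1:900")
  ddPad <- rbind(dd, c(0L, 0L))
  ffPad <- rbind(ff, data.frame(chrom = "chr1", pos = 900L))
  pad <- loadTable(ddPad, keysPad, dn, ffPad)
  expect_equal(pad$load, base$load)

  # duplicating the genome (every site twice) leaves the ratio unchanged
  dn2 <- rbind(dn, data.frame(chrom = "chr2", pos = 100L))
  ff2 <- rbind(ff, data.frame(chrom = "chr2", pos = c(200L, 250L)))
  dup <- loadTable(rbind(dd, dd),
                   c(keys, sub("chr1", "chr2", keys)), dn2, ff2)
  expect_equal(dup$load, base$load)
})

test_that("clade summaries rank medians and adjust pairwise tests", {
  reports <- data.frame(
    sample = sprintf("s%02d", 1:12),
    load = c(rep(0.1, 6), rep(0.2, 6)),
    undefined = FALSE)
  cm <- data.frame(sample = reports$sample,
                   clade = rep(c("A", "B"), each = 6))
  res <- cladeLoadTable(reports, cm)
  expect_equal(res$clades$median[res$clades$clade == "A"], 0.1)
  expect_equal(res$clades$median[res$clades$clade == "B"], 0.2)

  # two identical clades: median difference 0, p near 1
  cmSame <- data.frame(sample = reports$sample,
                       clade = rep(c("X", "Y"), 6))
  resSame <- cladeLoadTable(reports, cmSame)
  expect_equal(diff(resSame$clades$median), 0)
  expect_gt(resSame$tests$p[1], 0.9)

  # singleton clades keep their median but are excluded from tests
  cm1 <- data.frame(sample = reports$sample,
                    clade = c("solo", rep(c("A", "B"), c(5, 6))))
  res1 <- cladeLoadTable(reports, cm1)
  expect_true("solo" %in% res1$clades$clade)
  expect_false("solo" %in% c(res1$tests$cladeA, res1$tests$cladeB))
})

test_that("pairwise tests carry BH-adjusted p-values", {
  set.seed(3)
  reports <- data.frame(
    sample = sprintf("s%02d", 1:18),
    load = c(runif(6, 0, 0.1), runif(6, 0.1, 0.2), runif(6, 0.25, 0.3)),
    undefined = FALSE)
  cm <- data.frame(sample = reports$sample,
                   clade = rep(c("A", "B", "C"), each = 6))
  res <- cladeLoadTable(reports, cm)
  expect_equal(nrow(res$tests), 3L)
  # hand-applied step-up on the reported raw p-values
  p <- res$tests$p
  o <- order(p)
  stepUp <- pmin(1, rev(cummin(rev(p[o] * 3 / seq_len(3)))))
  expect_equal(res$tests$padj[o], stepUp)
})

test_that("pi_s-load relation reports both correlations and flags
           degenerate input", {
  pis <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(pisLoadRelation(pis, pis * 2 + 1)$pearson, 1)
  anti <- c(a = 4, b = 3, c = 2, d = 1)
  expect_equal(pisLoadRelation(pis, anti)$spearman, -1)
  expect_warning(res <- pisLoadRelation(pis, c(a = 1, b = 1, c = 1, d = 1)),
                 "constant")
  expect_true(res$degenerate)
})

test_that("rare fraction counts the sub-threshold spectrum mass", {
  sfs <- computeSFS(c(rep(1, 8), 2, 3), rep(4, 10), 4)
  expect_equal(rareFraction(sfs, 0.3), 0.8)  # only 1/4 < 0.3
  expect_equal(rareFraction(sfs, 1.0), 1.0)
  empty <- computeSFS(numeric(0), numeric(0), 4)
  expect_warning(expect_true(is.na(rareFraction(empty, 0.1))), "empty")
})
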