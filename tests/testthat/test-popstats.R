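test_that("site pi matches hand values and the pairwise-enumeration oracle", {
  expect_equal(sitePi(2, 4), 2 / 3)
  expect_equal(sitePi(0, 10), 0)
  expect_true(is.na(sitePi(1, 1)))
  for (n in 2:8) {
    for (c in 0:n) {
      expect_equal(sitePi(c, n), oraclePiPairwise(c, n))
    }
  }
})

test_that("windowed pi divides by window length and handles empty windows", {
  # one SNP with site pi = 2/3 (c = 2 of n = 4 haplotypes) in a 10 kb window
  gd <- makeDataset(matrix(c(1L, 1L), 1, 2), pos = 5000L)
  tr <- windowedPi(gd, windowBp = 10000L, stepBp = 10000L,
                   chromLengths = c(chr1 = 20000L))
  expect_equal(tr$value[1], (2 / 3) / 10000)
  expect_equal(tr$n_snps, c(1L, 0L))
  expect_equal(tr$value[2], 0)  # no SNPs: 0, not missing

  # chromosome shorter than the window: one truncated, flagged window
  expect_warning(
    tr2 <- windowedPi(gd, windowBp = 50000L, stepBp = 10000L,
                      chromLengths = c(chr1 = 20000L)),
    "truncated")
  expect_equal(nrow(tr2), 1L)
  expect_true(tr2$truncated)
  expect_equal(tr2$value, (2 / 3) / 20000)
})

test_that("pi track is invariant to sample order and allele swapping", {
  set.seed(9)
  dosage <- matrix(sample(0:2, 60, replace = TRUE), 10, 6)
  gd <- makeDataset(dosage, pos = sort(sample(1:40000, 10)))
  tr <- windowedPi(gd, windowBp = 10000L, stepBp = 5000L,
                   chromLengths = c(chr1 = 40000L))
  gdShuf <- gd[, c(4, 2, 6, 1, 3, 5)]
  trShuf <- windowedPi(gdShuf, windowBp = 10000L, stepBp = 5000L,
                       chromLengths = c(chr1 = 40000L))
  expect_equal(tr$value, trShuf$value)
  # swap ref/alt with dosage flip
  gdSwap <- makeDataset(2L - dosage, pos = siteInfo(gd)$pos,
                        ref = siteInfo(gd)$alt, alt = siteInfo(gd)$ref)
  trSwap <- windowedPi(gdSwap, windowBp = 10000L, stepBp = 5000L,
                       chromLengths = c(chr1 = 40000L))
  expect_equal(tr$value, trSwap$value)
})

test_that("interior SNPs appear in exactly windowBp/stepBp sliding windows", {
  gd <- makeDataset(matrix(c(1L, 0L, 1L, 0L), 1, 4), pos = 52341L)
  tr <- windowedPi(gd, windowBp = 50000L, stepBp = 10000L,
                   chromLengths = c(chr1 = 200000L))
  expect_equal(sum(tr$n_snps), 5L)
})

test_that("Weir-Cockerham components match the textbook transcription", {
  # fixed difference between 10 and 10 diploids: site FST = 1
  w <- wcFstSite(20, 20, 0, 20)
  expect_equal(unname(w["a"] / sum(w)), 1)

  # identical intermediate frequencies: a component can go negative
  w2 <- wcFstSite(10, 20, 10, 20)
  expect_lt(w2[["a"]], 0)

  set.seed(31)
  for (i in 1:100) {
    n1 <- 2 * sample(2:30, 1); n2 <- 2 * sample(2:30, 1)
    c1 <- sample(0:n1, 1); c2 <- sample(0:n2, 1)
    expect_equal(unname(wcFstSite(c1, n1, c2, n2)),
                 unname(oracleWC84(c1, n1, c2, n2)), tolerance = 1e-12)
  }
})

test_that("windowed FST is a ratio of sums with sane degenerate behavior", {
  set.seed(17)
  dosage <- matrix(sample(0:2, 80, replace = TRUE, prob = c(4, 2, 1)), 8, 10)
  gd <- makeDataset(dosage, pos = sort(sample(1:9000, 8)))
  a <- sampleIds(gd)[1:5]; b <- sampleIds(gd)[6:10]
  # single-site windows equal the site estimate
  tr <- windowedFst(gd, a, b, windowBp = 10000L, stepBp = 10000L,
                    chromLengths = c(chr1 = 10000L), minSnps = 1L)
  ac <- lapply(list(a, b), function(g) {
    d <- dosages(gd)[, g]
    list(c = rowSums(d), n = 2 * rowSums(!is.na(d)))
  })
  comp <- wcFstSite(ac[[1]]$c, ac[[1]]$n, ac[[2]]$c, ac[[2]]$n)
  expect_equal(tr$value[1], sum(comp[, "a"]) / sum(comp))

  # monomorphic-everywhere window: zero denominator gives NA
  gd0 <- makeDataset(matrix(0L, 2, 10))
  gd0@dosage[1, 1] <- 0L
  tr0 <- windowedFst(gd0, a, b, windowBp = 10000L, stepBp = 10000L,
                     chromLengths = c(chr1 = 10000L), minSnps = 1L)
  expect_true(is.na(tr0$value[1]))
})

test_that("SFS projection counts, conserves mass, and guards projection
           size", {
  # 3 fully called sites with derived counts {1, 1, 2} in n = 4
  sfs <- computeSFS(c(1, 1, 2), c(4, 4, 4), 4)
  expect_equal(sfs$nSites, c(2, 1, 0))

  # projection conserves total mass (including the excluded 0/n classes)
  set.seed(12)
  K <- sample(0:20, 50, replace = TRUE)
  N <- rep(20, 50)
  sfs2 <- computeSFS(K, N, 10)
  inner <- sum(sfs2$nSites)
  edge <- sum(vapply(seq_along(K), function(j)
    dhyper(0, K[j], N[j] - K[j], 10) + dhyper(10, K[j], N[j] - K[j], 10), 0))
  expect_equal(inner + edge, 50)

  # refusing to project when most sites have too few called haplotypes
  expect_error(computeSFS(c(1, 1, 1), c(10, 4, 4), 8), "projection")
})
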