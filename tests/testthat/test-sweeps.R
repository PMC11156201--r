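makeTrack <- function(values, windowBp = 10000L) {
  n <- length(values)
  data.frame(chrom = "chr1", start = (seq_len(n) - 1L) * windowBp,
             end = seq_len(n) * windowBp, n_snps = 10L, value = values,
             truncated = FALSE, stringsAsFactors = FALSE)
}

test_that("top-quantile windows use order statistics with tie inclusion", {
  tr <- makeTrack(as.numeric(1:100))
  top <- topQuantileWindows(tr, 0.05)
  expect_setequal(top$value, 96:100)

  # constant track: everything ties at the cutoff
  expect_warning(all <- topQuantileWindows(makeTrack(rep(1, 20)), 0.05),
                 "constant")
  expect_equal(nrow(all), 20L)

  # missing values are excluded from the quantile
  trNA <- makeTrack(c(rep(NA_real_, 10), as.numeric(1:20)))
  topNA <- topQuantileWindows(trNA, 0.1)
  expect_setequal(topNA$value, c(19, 20))

  expect_error(topQuantileWindows(makeTrack(rep(NA_real_, 4)), 0.05),
               "non-missing")

  # random tracks match the sort-and-slice oracle, and the outlier count
  # stays within [ceil(q m), m]
  set.seed(8)
  for (i in 1:25) {
    v <- sample(round(rnorm(40), 2), 60, replace = TRUE)
    tr <- makeTrack(v)
    got <- topQuantileWindows(tr, 0.05)
    expect_setequal(got$start, tr$start[oracleTopWindows(v, 0.05)])
    expect_gte(nrow(got), ceiling(0.05 * sum(!is.na(v))))
    expect_lte(nrow(got), length(v))
  }
})

test_that("window intersection and gene mapping deduplicate and validate
           grids", {
  tr <- makeTrack(as.numeric(1:10))
  genes <- data.frame(geneId = c("g1", "g2", "g3"),
                      chrom = "chr1",
                      start = c(25001L, 29500L, 95000L),
                      end = c(26000L, 31000L, 96000L))
  a <- tr[1:5, ]; b <- tr[3:7, ]
  cs <- intersectAndMap(a, b, genes, comparison = "toy")
  expect_equal(cs$windows$start, tr$start[3:5])
  # g1 inside window 3; g2 spans the window 3/4 boundary -> listed once
  expect_equal(cs$genes, c("g1", "g2"))

  # idempotence: A intersected with itself returns A's outliers
  csAA <- intersectAndMap(a, a, genes)
  expect_equal(csAA$windows, a)

  # mismatched grids are refused
  b2 <- b; b2$end <- b2$end + 5000L
  expect_error(intersectAndMap(a, b2, genes), "grids differ")
})

test_that("parallel candidates are a plain set intersection", {
  expect_equal(parallelCandidates(c("g1", "g2", "g3"), c("g2", "g3", "g4")),
               c("g2", "g3"))
  expect_equal(parallelCandidates(c("g1"), c("g2")), character(0))
  expect_equal(parallelCandidates(c("g2", "g1"), c("g1", "g2")),
               c("g1", "g2"))
})

test_that("carrier frequencies split by clade", {
  dosage <- matrix(c(0L, 0L, 1L, 2L, NA,
                     2L, 2L, 2L, 2L, 2L), nrow = 2, byrow = TRUE,
                   dimnames = list(NULL, sprintf("s%d", 1:5)))
  gd <- makeDataset(dosage, pos = c(100L, 200L))
  cm <- data.frame(sample = sprintf("s%d", 1:5),
                   clade = c("A", "A", "A", "A", "B"))
  cf <- carrierFrequency(gd, cm, "chr1", 100L, "G")
  expect_equal(cf$carrierProp[cf$clade == "A"], 0.5)
  expect_equal(cf$daf[cf$clade == "A"], 3 / 8)
  expect_true(is.na(cf$carrierProp[cf$clade == "B"]))  # only missing calls

  # all hom-derived: carrier and DAF both 1; ref-derived flips dosages
  cf2 <- carrierFrequency(gd, cm, "chr1", 200L, "G")
  expect_equal(cf2$carrierProp, c(1, 1))
  expect_equal(cf2$daf, c(1, 1))
  cf3 <- carrierFrequency(gd, cm, "chr1", 200L, "A")
  expect_equal(cf3$daf, c(0, 0))

  expect_error(carrierFrequency(gd, cm, "chr1", 999L, "G"), "not in dataset")
  expect_error(carrierFrequency(gd, cm, "chr1", 100L, "T"), "neither")
})
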