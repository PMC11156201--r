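test_that("VCF ingestion keeps biallelic SNPs and tracks exclusions", {
  path <- writeToyVCF()
  expect_message(ds <- readVCF(path), "dropped")
  expect_equal(nSites(ds), 3L)  # tri-allelic and indel records excluded
  expect_equal(attr(ds, "excluded"),
               c(multiallelic = 1L, nonSNP = 1L))
  expect_equal(sampleIds(ds), c("s1", "s2", "s3"))
  d <- dosages(ds)
  expect_equal(unname(d[siteInfo(ds)$pos == 100, ]), c(0L, 1L, 2L))
  # "./." becomes a missing dosage
  expect_true(is.na(d[siteInfo(ds)$pos == 200, "s1"]))
  expect_equal(unname(callDepth(ds)[siteInfo(ds)$pos == 100, ]), c(9, 8, 7))
})

test_that("write/read round-trips a dataset", {
  set.seed(11)
  dosage <- matrix(sample(c(0:2, NA), 40, replace = TRUE), 10, 4)
  gd <- makeDataset(dosage, chrom = rep(c("chr1", "chr2"), each = 5),
                    pos = rep(1:5 * 100L, 2),
                    ref = rep(c("A", "C"), 5), alt = rep(c("G", "T"), 5))
  path <- file.path(tempfile("rt_"), "x.vcf")
  dir.create(dirname(path))
  writeVCF(gd, path)
  back <- readVCF(path)
  expect_equal(dosages(back), dosages(gd))
  expect_equal(siteInfo(back), siteInfo(gd))
})

test_that("a header-only VCF yields an empty dataset", {
  dir <- tempfile("empty_"); dir.create(dir)
  path <- file.path(dir, "empty.vcf")
  writeVCF(makeDataset(matrix(integer(0), 0, 2)), path)
  ds <- suppressWarnings(readVCF(path))
  expect_equal(nSites(ds), 0L)
})

test_that("variant filter applies depth, missingness and MAF rules", {
  # 10 samples; site 1: 3 missing calls (0.7 called < 0.8); site 2: alt
  # frequency 0.04 < 0.05 via depth-masked call; site 3 passes
  dosage <- rbind(c(rep(0L, 7), NA, NA, NA),
                  c(1L, rep(0L, 9)),
                  c(rep(1L, 5), rep(0L, 5)))
  depth <- rbind(rep(10, 10), c(2, rep(10, 9)), rep(10, 10))
  gd <- makeDataset(dosage, depth = depth)
  # site 2: depth<3 masks the only alt carrier -> monomorphic, MAF 0
  fl <- filterVariants(gd, minCalled = 0.8, minMaf = 0.05, minDepth = 3)
  expect_equal(nSites(fl$dataset), 1L)
  expect_equal(unname(fl$counts),
               c(1L, 1L, 1L))  # lowDepthCalls, missingness, maf

  # maf strictly below the threshold is removed; at threshold kept
  d2 <- rbind(c(1L, rep(0L, 9)), c(1L, rep(0L, 9)))  # maf 0.05
  gd2 <- makeDataset(d2)
  fl2 <- suppressWarnings(filterVariants(gd2, minCalled = 0.8,
                                         minMaf = 0.05, minDepth = 0))
  expect_equal(nSites(fl2$dataset), 2L)

  # all thresholds zero is the identity
  fl3 <- filterVariants(gd, minCalled = 0, minMaf = 0, minDepth = 0)
  expect_equal(dosages(fl3$dataset), dosages(gd))

  # idempotence: filtering twice equals filtering once
  fl4 <- filterVariants(fl$dataset, minCalled = 0.8, minMaf = 0.05,
                        minDepth = 3)
  expect_equal(dosages(fl4$dataset), dosages(fl$dataset))
  expect_equal(unname(fl4$counts), c(0L, 0L, 0L))
})

test_that("depth filter is skipped with a warning when depth is absent", {
  gd <- makeDataset(rbind(c(1L, 0L, 1L, 0L)))
  expect_warning(filterVariants(gd, minCalled = 0, minMaf = 0, minDepth = 3),
                 "depth")
})

test_that("window score tracks are sorted, NA-tolerant and duplicate-free", {
  dir <- tempfile("ws_"); dir.create(dir)
  path <- file.path(dir, "scores.tsv")
  writeLines(c("chrom\tstart\tend\tscore",
               "chr1\t20000\t30000\t2.5",
               "chr1\t0\t10000\t1.0",
               "chr2\t0\t10000\tNA",
               "chr1\t10000\t20000\t7.25",
               "chr2\t10000\t20000\t3.0"), path)
  tr <- readWindowScores(path)
  expect_equal(nrow(tr), 5L)
  expect_equal(tr$start[tr$chrom == "chr1"], c(0L, 10000L, 20000L))
  expect_true(is.na(tr$value[tr$chrom == "chr2" & tr$start == 0]))

  writeLines(c("chrom\tstart\tend\tscore",
               "chr1\t0\t10000\t1.0",
               "chr1\t0\t10000\t2.0"), path)
  expect_error(readWindowScores(path), "duplicated")
})
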