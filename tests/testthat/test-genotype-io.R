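test_that("ped/map parsing recodes genotypes, missing and autosomes", {
  dir <- withr::local_tempdir()
  writeLines(c("1 snpA 0 100", "1 snpB 0 200", "X snpX 0 50"),
             file.path(dir, "toy.map"))
  writeLines(c("F1 s1 0 0 1 -9 A A A G C C",
               "F1 s2 0 0 2 -9 A G 0 0 C C"),
             file.path(dir, "toy.ped"))
  ds <- read_plink_text(file.path(dir, "toy.ped"), file.path(dir, "toy.map"))

  expect_equal(nrow(ds$snps), 2)              # X dropped
  expect_false("snpX" %in% ds$snps$snp_id)
  expect_equal(sum(is.na(ds$calls)), 1)       # the single 0 0 genotype
  # snpA: A is the major allele -> a2 = A, s1 (AA) carries 2 copies
  expect_equal(ds$snps$a2[ds$snps$snp_id == "snpA"], "A")
  expect_equal(unname(ds$calls["s1", "snpA"]), 2L)
  expect_equal(unname(ds$calls["s2", "snpA"]), 1L)
})

test_that("text parser rejects malformed and multi-allelic input", {
  dir <- withr::local_tempdir()
  writeLines(c("1 snpA 0 100"), file.path(dir, "m.map"))
  writeLines(c("F s1 0 0 0 -9 A A", "F s2 0 0 0 -9 A"),
             file.path(dir, "bad.ped"))
  expect_error(read_plink_text(file.path(dir, "bad.ped"),
                               file.path(dir, "m.map")), "line 2")
  writeLines(c("F s1 0 0 0 -9 A C", "F s2 0 0 0 -9 G G"),
             file.path(dir, "tri.ped"))
  expect_error(read_plink_text(file.path(dir, "tri.ped"),
                               file.path(dir, "m.map")),
               "more than 2 alleles")
})

test_that("binary round trip is lossless and truncation is caught", {
  ds <- rand_ds(1, n_samples = 4, n_snps = 5)
  pre <- tempfile()
  write_plink_binary(ds, pre)
  ds2 <- read_plink_binary(paste0(pre, ".bed"), paste0(pre, ".bim"),
                           paste0(pre, ".fam"))
  expect_identical(unname(ds2$calls), unname(ds$calls))
  expect_equal(ds2$snps, ds$snps)
  expect_equal(ds2$samples$sample_id, ds$samples$sample_id)

  raw <- readBin(paste0(pre, ".bed"), "raw", 100)
  writeBin(raw[-length(raw)], paste0(pre, ".bed"))
  expect_error(read_plink_binary(paste0(pre, ".bed"), paste0(pre, ".bim"),
                                 paste0(pre, ".fam")), "truncated")
  writeBin(as.raw(c(0, 0, 0, raw[-(1:3)])), paste0(pre, ".bed"))
  expect_error(read_plink_binary(paste0(pre, ".bed"), paste0(pre, ".bim"),
                                 paste0(pre, ".fam")), "magic")
})

test_that("text and binary encodings decode to the same dataset", {
  ds <- rand_ds(7, n_samples = 5, n_snps = 8, missing_rate = 0.1)
  pre <- tempfile()
  write_plink_text(ds, pre)
  write_plink_binary(ds, pre)
  from_text <- read_plink_text(paste0(pre, ".ped"), paste0(pre, ".map"))
  from_bin <- read_plink_binary(paste0(pre, ".bed"), paste0(pre, ".bim"),
                                paste0(pre, ".fam"))
  # same missing pattern and heterozygote pattern regardless of allele
  # labelling convention; binary (explicit alleles) must round-trip calls
  expect_identical(is.na(from_text$calls), is.na(from_bin$calls))
  expect_identical(from_text$calls == 1L, from_bin$calls == 1L)
  expect_identical(unname(from_bin$calls), unname(ds$calls))

  # independent hand-decoding of the first SNP's bed bytes
  raw <- readBin(paste0(pre, ".bed"), "raw", 1000)
  expect_identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01)))
  bits <- as.integer(rawToBits(raw[4:5]))   # 5 samples -> 2 bytes per SNP
  codes <- bits[seq(1, 20, 2)] + 2 * bits[seq(2, 20, 2)]
  decode <- c(`0` = 0L, `1` = NA, `2` = 1L, `3` = 2L)
  expect_equal(unname(decode[as.character(codes[1:5])]),
               unname(ds$calls[, 1]))
})

test_that("round-trip is lossless for both dialects on random datasets", {
  for (seed in 1:5) {
    ds <- rand_ds(seed, n_samples = 3 + seed, n_snps = 30,
                  missing_rate = 0.05)
    pre <- tempfile()
    write_plink_binary(ds, pre)
    expect_identical(
      unname(read_plink(pre)$calls), unname(ds$calls))
    pre2 <- tempfile()
    write_plink_text(ds, pre2)
    back <- read_plink(pre2)
    expect_identical(is.na(back$calls), is.na(ds$calls))
    expect_identical(back$calls == 1L, ds$calls == 1L)
    expect_equal(back$samples$sample_id, ds$samples$sample_id)
    expect_equal(back$snps$bp, ds$snps$bp)
  }
})

test_that("subset is order-preserving, composable and validated", {
  ds <- rand_ds(3, n_samples = 6, n_snps = 20)
  expect_equal(subset_geno(ds, ds$samples$sample_id, ds$snps$snp_id), ds)
  one <- subset_geno(ds, sample_ids = "ind3")
  expect_equal(nrow(one$calls), 1)
  a <- c("ind1", "ind2", "ind4", "ind5")
  b <- c("ind2", "ind5")
  expect_equal(subset_geno(subset_geno(ds, a), b), subset_geno(ds, b))
  # shuffled id set still yields dataset order
  expect_equal(subset_geno(ds, rev(a))$samples$sample_id,
               intersect(ds$samples$sample_id, a))
  expect_error(subset_geno(ds, "nope"), "unknown sample")
  expect_error(subset_geno(ds, snp_ids = "nope"), "unknown SNP")
})

test_that("SNPs emerge position-sorted per chromosome", {
  set.seed(9)
  ds <- rand_ds(9, n_snps = 40, n_chrom = 3)
  pre <- tempfile()
  # shuffle before writing; reader must restore order
  perm <- sample(nrow(ds$snps))
  shuffled <- geno_ds(ds$calls[, perm], ds$snps[perm, ], ds$samples)
  write_plink_text(shuffled, pre)
  back <- read_plink(pre)
  for (ch in unique(back$snps$chrom))
    expect_false(is.unsorted(back$snps$bp[back$snps$chrom == ch]))
  expect_equal(back$samples$sample_id, ds$samples$sample_id)
})
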