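test_that("ROH construction examples behave per the window rules", {
  # fully heterozygous sample: no segments
  het <- ds_from_calls(matrix(1L, 1, 100),
                       bp = seq(5e4, by = 5e4, length.out = 100))
  expect_equal(nrow(suppressWarnings(detect_roh(het))), 0)

  # 100 homozygous SNPs evenly spaced 50 kb: one segment spanning all
  hom <- ds_from_calls(matrix(0L, 1, 100),
                       bp = seq(5e4, by = 5e4, length.out = 100))
  seg <- detect_roh(hom)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_bp, 5e4)
  expect_equal(seg$end_bp, 5e6)
  expect_equal(seg$n_snps, 100)

  # 60 homozygous SNPs spanning only 400 kb fail the 500 kb rule
  calls <- matrix(1L, 1, 200)
  calls[1, 71:130] <- 0L
  bp <- c(seq(1e5, by = 1e5, length.out = 70),
          seq(7.1e6, by = 4e5 / 59, length.out = 60),
          seq(1.2e7, by = 1e5, length.out = 70))
  ds <- ds_from_calls(calls, bp = round(bp))
  expect_equal(nrow(detect_roh(ds)), 0)
})

test_that("detect_roh equals the brute-force rule enumeration", {
  for (seed in 1:20) {
    set.seed(seed)
    n_snps <- sample(50:200, 1)
    n_samples <- sample(2:10, 1)
    # mostly-homozygous genotypes so runs actually form
    calls <- matrix(sample(c(0L, 0L, 2L, 2L, 1L, NA), n_snps * n_samples,
                           replace = TRUE,
                           prob = c(0.4, 0.2, 0.2, 0.1, 0.06, 0.04)),
                    nrow = n_samples)
    chrom <- sort(sample(c("1", "2"), n_snps, replace = TRUE))
    bp <- unlist(lapply(unique(chrom), function(ch)
      sort(sample.int(3e7, sum(chrom == ch)))))
    ds <- ds_from_calls(calls, bp = bp, chrom = chrom)
    cfg <- roh_config()
    got <- suppressWarnings(detect_roh(ds, cfg))
    want <- oracle_roh(ds, cfg)
    attr(got, "config") <- NULL
    class(got) <- "data.frame"
    o <- function(d) d[order(d$sample_id, d$chrom, d$start_bp), ]
    expect_equal(o(got), o(want), ignore_attr = TRUE,
                 info = paste("seed", seed))
  }
})

test_that("F_ROH is the ROH fraction of the SNP-covered genome", {
  ds <- ds_from_calls(matrix(1L, 2, 4), bp = c(1, 4e7, 6e7, 1e8))
  segs <- data.frame(sample_id = "ind1", chrom = "1", start_bp = 1e7,
                     end_bp = 2e7 - 1, n_snps = 100, length_bp = 1e7)
  froh <- compute_froh(segs, ds)
  expect_equal(attr(froh, "l_auto_bp"), 1e8)
  expect_equal(froh$f_roh[froh$sample_id == "ind1"], 0.10)
  expect_equal(froh$f_roh[froh$sample_id == "ind2"], 0)   # no segments
})

test_that("planted autozygous fractions are recovered within 0.02", {
  tracts <- list(
    q05 = data.frame(chrom = "1", start_bp = 2e7, end_bp = 2.6e7 - 1),
    q10 = data.frame(chrom = c("1", "2"), start_bp = c(1e7, 3e7),
                     end_bp = c(1.7e7 - 1, 3.5e7 - 1)),
    q25 = data.frame(chrom = c("1", "2"), start_bp = c(5e6, 1e7),
                     end_bp = c(2e7 - 1, 2.5e7 - 1)))
  sim <- outbred_sim(61, n_samples = 6, n_chrom = 2,
                     chrom_length_bp = 6e7, spacing = 5e4,
                     planted_autozygosity = list(
                       list(sample = 1, tracts = tracts$q05),
                       list(sample = 2, tracts = tracts$q10),
                       list(sample = 3, tracts = tracts$q25)))
  froh <- compute_froh(suppressWarnings(detect_roh(sim$ds)), sim$ds)
  l_auto <- attr(froh, "l_auto_bp")
  q <- vapply(tracts, function(t) sum(t$end_bp - t$start_bp + 1), 0) /
    l_auto
  expect_equal(froh$f_roh[1], unname(q[1]), tolerance = 0.02 / q[1])
  expect_equal(froh$f_roh[2], unname(q[2]), tolerance = 0.02 / q[2])
  expect_equal(froh$f_roh[3], unname(q[3]), tolerance = 0.02 / q[3])
})

test_that("fully outbred samples accrue almost no ROH length", {
  sim <- outbred_sim(62, n_samples = 10, n_chrom = 2,
                     chrom_length_bp = 6e7, spacing = 5e4)
  froh <- compute_froh(suppressWarnings(detect_roh(sim$ds)), sim$ds)
  expect_lte(max(froh$f_roh), 0.02)
})

test_that("lowering min_length_kb never decreases total ROH length", {
  sim <- outbred_sim(63, n_samples = 4, n_chrom = 1,
                     chrom_length_bp = 3e7, spacing = 5e4,
                     planted_autozygosity = list(
                       list(sample = 1, tracts = data.frame(
                         chrom = "1", start_bp = 1e7, end_bp = 1.3e7))))
  tot <- vapply(c(2000, 1000, 500, 250), function(ml) {
    seg <- suppressWarnings(detect_roh(sim$ds,
                                       roh_config(min_length_kb = ml)))
    sum(seg$length_bp)
  }, 0)
  expect_true(all(diff(tot) >= 0))
})

test_that("F_ROH is invariant under allele-coding swap", {
  sim <- outbred_sim(64, n_samples = 4, n_chrom = 1,
                     chrom_length_bp = 3e7, spacing = 5e4,
                     planted_autozygosity = list(
                       list(sample = 2, tracts = data.frame(
                         chrom = "1", start_bp = 5e6, end_bp = 9e6))))
  ds <- sim$ds
  swapped <- ds
  swapped$calls <- 2L - ds$calls
  f1 <- compute_froh(suppressWarnings(detect_roh(ds)), ds)
  f2 <- compute_froh(suppressWarnings(detect_roh(swapped)), swapped)
  expect_equal(f1$f_roh, f2$f_roh)
})

test_that("rank-sum comparison matches enumeration and Bonferroni", {
  a <- c(0.1, 0.2, 0.3)
  b <- c(0.4, 0.5, 0.6)
  froh <- data.frame(population = rep(c("A", "B"), each = 3),
                     f_roh = c(a, b))
  cmp <- compare_froh(froh)
  expect_equal(cmp$p_raw, oracle_wilcoxon(a, b))
  expect_equal(cmp$p_raw, 2 / 20)   # both one-sided extremes of 20 splits

  # enumeration agreement across random untied small groups
  for (seed in 1:10) {
    set.seed(seed)
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    x <- sample(seq(0.01, 0.99, 0.01), na + nb)   # distinct values
    f <- data.frame(population = rep(c("A", "B"), c(na, nb)), f_roh = x)
    expect_equal(compare_froh(f)$p_raw,
                 oracle_wilcoxon(x[1:na], x[-(1:na)]),
                 info = paste("seed", seed))
  }

  # 5 populations -> 10 comparisons, Bonferroni arithmetic
  set.seed(77)
  f5 <- data.frame(population = rep(LETTERS[1:5], each = 4),
                   f_roh = runif(20))
  cmp5 <- compare_froh(f5)
  expect_equal(nrow(cmp5), 10)
  expect_equal(cmp5$p_adjusted, pmin(1, cmp5$p_raw * 10))

  # identical multisets sit at the null center
  same <- data.frame(population = rep(c("A", "B"), each = 4),
                     f_roh = rep(c(0.1, 0.2, 0.3, 0.4), 2))
  expect_gt(compare_froh(same)$p_raw, 0.9)

  # degenerate: all values equal
  flat <- data.frame(population = rep(c("A", "B"), each = 3),
                     f_roh = rep(0.1, 6))
  expect_warning(cmp_flat <- compare_froh(flat), "degenerate")
  expect_equal(cmp_flat$p_raw, 1)
})
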