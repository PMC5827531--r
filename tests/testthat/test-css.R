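test_that("Weir-Cockerham theta matches fixation, null and hand cases", {
  # populations fixed for alternate alleles
  fixed <- ds_from_calls(rbind(matrix(0L, 10, 5), matrix(2L, 10, 5)),
                         pop = rep(c("T", "R"), each = 10))
  expect_equal(fst_per_snp(fixed, "T", "R")$fst, rep(1, 5))

  # identical allele frequencies, large n -> theta ~ 0
  set.seed(81)
  p <- runif(200, 0.2, 0.8)
  null_ds <- ds_from_calls(
    matrix(rbinom(300 * 200, 2, rep(p, each = 300)), nrow = 300),
    bp = seq_len(200) * 1e5, pop = rep(c("T", "R"), each = 150))
  th <- fst_per_snp(null_ds, "T", "R")$fst
  expect_lt(abs(mean(th)), 0.02)

  # hand-computed value: pop1 10 AA; pop2 5 AA + 5 Aa (A = a2)
  ds <- ds_from_calls(rbind(matrix(2L, 10, 1),
                            matrix(c(rep(2L, 5), rep(1L, 5)), 10, 1)),
                      pop = rep(c("T", "R"), each = 10))
  expect_equal(fst_per_snp(ds, "T", "R")$fst, 2 / 9)
  expect_equal(fst_per_snp(ds, "T", "R")$fst,
               oracle_wc_theta(list(c(10, 0, 0), c(5, 5, 0))))
})

test_that("theta equals the brute-force variance components on random data", {
  for (seed in 1:15) {
    set.seed(seed)
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    g1 <- rbinom(n1, 2, runif(1, 0.1, 0.9))
    g2 <- rbinom(n2, 2, runif(1, 0.1, 0.9))
    ds <- ds_from_calls(matrix(c(g1, g2), ncol = 1),
                        pop = rep(c("T", "R"), c(n1, n2)))
    got <- fst_per_snp(ds, "T", "R")
    cnt <- function(g) c(sum(g == 2), sum(g == 1), sum(g == 0))
    want <- oracle_wc_theta(list(cnt(g1), cnt(g2)))
    if (got$flag == "monomorphic") expect_equal(got$fst, 0)
    else expect_equal(got$fst, want, info = paste("seed", seed))
  }
})

test_that("allele-frequency change is the absolute difference", {
  ds <- ds_from_calls(rbind(c(2L, 1L, 2L), c(2L, 1L, 2L),
                            c(0L, 1L, 0L), c(0L, 1L, 2L)),
                      pop = rep(c("T", "R"), each = 2))
  d <- delta_saf(ds, "T", "R")$dsaf
  expect_equal(d, c(1, 0, 0.5))
  # p_test 0.9, p_ref 0.3 -> 0.6
  ds2 <- ds_from_calls(matrix(c(rep(2L, 9), 0L,
                                rep(1L, 6), rep(0L, 4)), ncol = 1),
                       pop = rep(c("T", "R"), each = 10))
  expect_equal(delta_saf(ds2, "T", "R")$dsaf, abs(0.9 - 0.3))
})

test_that("iHH matches the exhaustive pair-counting oracle", {
  set.seed(83)
  cfg <- contrast_config("T", "R", ehh_decay_cutoff = 0.05,
                         ehh_max_extension_bp = 2e6,
                         ehh_gap_limit_bp = 2e5)
  # 4 hand-written haplotypes x 8 SNPs
  H <- rbind(c(1, 1, 0, 1, 0, 0, 1, 0),
             c(1, 1, 0, 1, 0, 1, 0, 0),
             c(0, 1, 0, 1, 1, 0, 1, 1),
             c(1, 0, 1, 1, 0, 0, 1, 0))
  bp <- c(1e5, 1.8e5, 2.9e5, 3.5e5, 4.9e5, 5.5e5, 7e5, 8.1e5)
  for (core in seq_along(bp)) {
    got <- herdgen:::.ihh_one_side(H, bp, core, -1L, cfg) +
      herdgen:::.ihh_one_side(H, bp, core, +1L, cfg)
    expect_equal(got, oracle_ihh(H, bp, core, cfg),
                 info = paste("core", core))
  }
  # larger random panels, including gap truncation
  for (seed in 1:5) {
    set.seed(seed)
    H2 <- matrix(rbinom(12 * 30, 1, 0.5), nrow = 12)
    bp2 <- sort(sample.int(3e6, 30))
    for (core in c(1, 15, 30)) {
      got <- herdgen:::.ihh_one_side(H2, bp2, core, -1L, cfg) +
        herdgen:::.ihh_one_side(H2, bp2, core, +1L, cfg)
      expect_equal(got, oracle_ihh(H2, bp2, core, cfg),
                   info = paste("seed", seed, "core", core))
    }
  }
})

test_that("xpehh sign convention and symmetry hold", {
  cfg <- contrast_config("T", "R")
  snps <- data.frame(chrom = "1", snp_id = paste0("s", 1:20),
                     bp = seq(1e5, by = 5e4, length.out = 20))
  set.seed(84)
  H <- matrix(rbinom(10 * 20, 1, 0.5), nrow = 10)
  same <- xpehh_scan(H, H, snps, cfg)
  expect_equal(same$xpehh_raw[!is.na(same$xpehh_raw)],
               rep(0, sum(!is.na(same$xpehh_raw))))
  # homogeneous test population vs diverse reference: raw > 0
  Hmono <- matrix(1, 10, 20)
  up <- xpehh_scan(Hmono, H, snps, cfg)
  expect_true(all(up$xpehh_raw[!is.na(up$xpehh_raw)] > 0))
})

test_that("CSS matches the step-by-step recomputation on a toy table", {
  set.seed(85)
  stats <- cbind(fst = runif(20), dsaf = runif(20), xpehh = rnorm(20))
  expect_equal(composite_selection_signal(stats), oracle_css(stats))
  # with ties
  stats2 <- stats
  stats2[3, 1] <- stats2[7, 1]
  expect_equal(composite_selection_signal(stats2), oracle_css(stats2))
  # single test: fractional ranks are i/(n+1) exactly
  x <- c(0.4, 0.1, 0.9)
  css1 <- composite_selection_signal(cbind(x))
  expect_equal(css1, -log10(1 - pnorm(qnorm(rank(x) / 4))))
  expect_error(composite_selection_signal(matrix(0, 5, 0)), "no constituent")
})

test_that("CSS is invariant under monotone transforms and ranks maxima top", {
  set.seed(86)
  stats <- cbind(a = rnorm(500), b = runif(500), c = rexp(500))
  css <- composite_selection_signal(stats)
  warped <- cbind(exp(stats[, "a"]), stats[, "b"]^3 + 5,
                  log(stats[, "c"] + 1))
  expect_equal(composite_selection_signal(warped), css)

  stats[17, ] <- apply(stats, 2, max) + 1   # maximal in every test
  expect_equal(which.max(composite_selection_signal(stats)), 17L)
})

test_that("1 Mb smoothing averages within tiled windows", {
  chrom <- rep("1", 4)
  bp <- c(2e5, 9e5, 1.5e6, 2.5e6)
  css <- c(1, 3, 5, 7)
  sm <- smooth_css(chrom, bp, css)
  expect_equal(sm, c(2, 2, 5, 7))
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  expect_equal(smooth_css(chrom[perm], bp[perm], css[perm]), sm[perm])
  # window boundary: bp 1e6 belongs to the first window (positions 1..1e6)
  expect_equal(smooth_css(c("1", "1"), c(1e6, 1e6 + 1), c(2, 4)), c(2, 4))
})

test_that("peak calling implements the flanking rule", {
  set.seed(87)
  n <- 10000
  scan <- data.frame(chrom = rep("1", n), bp = seq_len(n) * 5e4,
                     snp_id = paste0("s", seq_len(n)),
                     css = runif(n, 0, 1))
  # plant 7 adjacent inflated SNPs: 1 in top 0.1%, 6 in top 1%
  scan$css[5000] <- 10
  scan$css[c(4997:4999, 5001:5003)] <- 5
  pk <- call_peaks(scan)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peak_snp, "s5000")
  expect_gte(pk$flank_count, 5)
  expect_equal(pk$gene_window_start, scan$bp[5000] - 1e6)

  # isolated top SNP with no top-1% neighbours: no peak
  scan2 <- scan
  scan2$css[c(4997:4999, 5001:5003)] <- runif(6)
  expect_equal(nrow(call_peaks(scan2)), 0)

  expect_error(call_peaks(scan[1:500, ]), "fewer than 1000")
})

test_that("null scans rarely produce peaks; permutation destroys real ones", {
  hits <- 0
  for (seed in 1:60) {
    set.seed(seed)
    n <- 10000
    scan <- data.frame(chrom = rep(as.character(1:5), each = n / 5),
                       bp = rep(seq(5e4, by = 5e4, length.out = n / 5), 5),
                       snp_id = paste0("s", seq_len(n)),
                       css = runif(n))
    if (nrow(call_peaks(scan)) > 0) hits <- hits + 1
  }
  expect_lte(hits / 60, 0.10)

  set.seed(88)
  n <- 10000
  planted <- data.frame(chrom = rep("1", n), bp = seq_len(n) * 5e4,
                        snp_id = paste0("s", seq_len(n)), css = runif(n))
  planted$css[5000:5010] <- c(10, rep(5, 10))
  expect_gt(nrow(call_peaks(planted)), 0)
  set.seed(89)
  shuffled <- planted
  shuffled$css <- sample(shuffled$css)
  expect_equal(nrow(call_peaks(shuffled)), 0)
})
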