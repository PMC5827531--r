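# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles with plain loops, sharing no code with
# the package implementations they check.

# Exact HWE: absolute Levene-Haldane probabilities via the closed form
#   P(h) = n! / (naa! h! nbb!) * 2^h * na! nb! / (2n)!
# summed over heterozygote counts no more probable than the observed one.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  if (na == 0 || nb == 0) return(1)
  hets <- seq(na %% 2, min(na, nb), by = 2)
  prob <- vapply(hets, function(h) {
    exp(lfactorial(n) - lfactorial((na - h) / 2) - lfactorial(h) -
          lfactorial((nb - h) / 2) + h * log(2) +
          lfactorial(na) + lfactorial(nb) - lfactorial(2 * n))
  }, 0)
  sum(prob[prob <= prob[hets == n_ab] * (1 + 1e-9)])
}

# ROH rules re-applied naively: window compliance by explicit counting,
# SNP inclusion by looping over every spanning window, runs by scanning.
oracle_roh <- function(ds, cfg) {
  out <- list()
  for (ch in unique(ds$snps$chrom)) {
    jj <- which(ds$snps$chrom == ch)
    bp <- ds$snps$bp[jj]
    n <- length(jj)
    W <- min(cfg$window_snps, n)
    for (i in seq_len(nrow(ds$samples))) {
      g <- ds$calls[i, jj]
      cand <- logical(n)
      for (s in seq_len(n)) {
        n_win <- 0; n_ok <- 0
        for (w0 in max(1, s - W + 1):min(s, n - W + 1)) {
          win <- g[w0:(w0 + W - 1)]
          n_win <- n_win + 1
          if (sum(win == 1, na.rm = TRUE) <= cfg$max_het_per_window &&
              sum(is.na(win)) <= cfg$max_missing_per_window)
            n_ok <- n_ok + 1
        }
        cand[s] <- (n_ok / n_win) >= cfg$window_hit_fraction
      }
      s <- 1
      while (s <= n) {
        if (!cand[s]) { s <- s + 1; next }
        e <- s
        while (e < n && cand[e + 1] &&
               (bp[e + 1] - bp[e]) <= cfg$max_internal_gap_kb * 1000)
          e <- e + 1
        len <- bp[e] - bp[s] + 1
        if (len >= cfg$min_length_kb * 1000 &&
            len / (e - s + 1) <= cfg$min_density_kb_per_snp * 1000)
          out[[length(out) + 1]] <- data.frame(
            sample_id = ds$samples$sample_id[i], chrom = ch,
            start_bp = bp[s], end_bp = bp[e], n_snps = e - s + 1,
            length_bp = len)
        s <- e + 1
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(sample_id = character(), chrom = character(),
                  start_bp = integer(), end_bp = integer(),
                  n_snps = integer(), length_bp = integer())
}

# Exact two-sided rank-sum P by enumerating every assignment of ranks.
oracle_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n <- length(pooled)
  r_obs <- sum(rank(pooled)[seq_along(a)])
  sets <- utils::combn(n, length(a))
  sums <- colSums(matrix(seq_len(n)[sets], nrow = length(a)))
  center <- length(a) * (n + 1) / 2
  mean(abs(sums - center) >= abs(r_obs - center) - 1e-9)
}

# Weir-Cockerham variance components computed with explicit per-population
# loops following the 1984 definitions.
oracle_wc_theta <- function(counts) {
  # counts: list of c(n_aa, n_ab, n_bb) per population (a = a2 allele)
  r <- length(counts)
  n <- vapply(counts, sum, 0)
  p <- vapply(counts, function(x) (2 * x[1] + x[2]) / (2 * sum(x)), 0)
  h <- vapply(counts, function(x) x[2] / sum(x), 0)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# EHH / iHH by exhaustive haplotype-pair counting with the same stopping
# rules (decay cutoff, extension cap, gap truncation).
oracle_ihh <- function(H, bp, core, cfg) {
  m <- nrow(H)
  pairs <- utils::combn(m, 2)
  ehh_at <- function(lo, hi) {
    same <- 0
    for (k in seq_len(ncol(pairs)))
      if (all(H[pairs[1, k], lo:hi] == H[pairs[2, k], lo:hi]))
        same <- same + 1
    same / ncol(pairs)
  }
  total <- 0
  for (step in c(-1, 1)) {
    ehh_prev <- ehh_at(core, core)
    if (ehh_prev < cfg$ehh_decay_cutoff) next
    pos_prev <- bp[core]
    j <- core + step
    while (j >= 1 && j <= length(bp)) {
      if (abs(bp[j] - pos_prev) > cfg$ehh_gap_limit_bp) break
      if (abs(bp[j] - bp[core]) > cfg$ehh_max_extension_bp) break
      e <- ehh_at(min(core, j), max(core, j))
      total <- total + (ehh_prev + e) / 2 * abs(bp[j] - pos_prev)
      if (e < cfg$ehh_decay_cutoff) break
      ehh_prev <- e
      pos_prev <- bp[j]
      j <- j + step
    }
  }
  total
}

# CSS recomputed step by step (sort-based fractional ranks, explicit
# per-test probit, explicit normal tail).
oracle_css <- function(stats) {
  n <- nrow(stats)
  k <- ncol(stats)
  zbar <- numeric(n)
  for (i in seq_len(n)) {
    zs <- numeric(k)
    for (j in seq_len(k)) {
      x <- stats[, j]
      rk <- (sum(x < x[i]) + (sum(x == x[i]) + 1) / 2)  # average rank
      zs[j] <- qnorm(rk / (n + 1))
    }
    zbar[i] <- mean(zs)
  }
  -log10(1 - pnorm(zbar / (1 / sqrt(k))))
}
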