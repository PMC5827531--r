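#' ROH detection configuration
#'
#' Sliding-window criteria for calling runs of homozygosity on 50K-density
#' array data: a 50-SNP window is advanced one SNP at a time; a window may
#' contain at most one heterozygous and at most two missing calls. A SNP
#' enters a candidate run when at least `window_hit_fraction` of the
#' windows spanning it are compliant (0.05, the usual default for this
#' scanning approach). Candidate runs are split at inter-SNP gaps above
#' `max_internal_gap_kb`, and a run qualifies as a ROH only if it is at
#' least `min_length_kb` long with at least one SNP per
#' `min_density_kb_per_snp`.
#'
#' @param min_length_kb minimum ROH length (kb).
#' @param min_density_kb_per_snp maximum kb of run length per SNP.
#' @param max_internal_gap_kb maximum gap between adjacent SNPs in a run
#'   (kb).
#' @param window_snps sliding-window size in SNPs.
#' @param max_het_per_window maximum heterozygous calls per window.
#' @param max_missing_per_window maximum missing calls per window.
#' @param window_hit_fraction minimum fraction of compliant spanning
#'   windows for a SNP to join a candidate run.
#' @return An `roh_config` list.
#' @export
roh_config <- function(min_length_kb = 500, min_density_kb_per_snp = 120,
                       max_internal_gap_kb = 1000, window_snps = 50,
                       max_het_per_window = 1, max_missing_per_window = 2,
                       window_hit_fraction = 0.05) {
  cfg <- list(min_length_kb = min_length_kb,
              min_density_kb_per_snp = min_density_kb_per_snp,
              max_internal_gap_kb = max_internal_gap_kb,
              window_snps = as.integer(window_snps),
              max_het_per_window = max_het_per_window,
              max_missing_per_window = max_missing_per_window,
              window_hit_fraction = window_hit_fraction)
  if (any(unlist(cfg) <= 0 & names(unlist(cfg)) != "window_hit_fraction"))
    stop("all ROH parameters must be positive")
  structure(cfg, class = "roh_config")
}

# Candidate-SNP flags for one genotype vector on one chromosome.
# Windows of W consecutive SNPs (truncated to the chromosome if it has
# fewer than W SNPs); a SNP is a candidate when the compliant fraction of
# its spanning windows reaches the hit fraction.
.roh_candidates <- function(g, cfg) {
  n <- length(g)
  W <- min(cfg$window_snps, n)
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  ch <- cumsum(c(0L, het))
  cm <- cumsum(c(0L, mis))
  starts <- seq_len(n - W + 1L)
  ok <- (ch[starts + W] - ch[starts]) <= cfg$max_het_per_window &
    (cm[starts + W] - cm[starts]) <= cfg$max_missing_per_window
  cok <- cumsum(c(0L, as.integer(ok)))
  i <- seq_len(n)
  lo <- pmax(1L, i - W + 1L)
  hi <- pmin(i, n - W + 1L)
  frac <- (cok[hi + 1L] - cok[lo]) / (hi - lo + 1L)
  frac >= cfg$window_hit_fraction
}

#' Detect runs of homozygosity
#'
#' Scans each sample and chromosome with the sliding-window criteria of
#' [roh_config()]. Reported segment boundaries are the outermost SNPs of
#' the qualifying run. Chromosomes with fewer SNPs than the window size
#' are evaluated with a single truncated window (with a warning). The SNP
#' set is used as given; for inbreeding work supply data filtered without
#' a MAF threshold.
#'
#' @param ds a [geno_ds()] with position-sorted SNPs.
#' @param cfg an [roh_config()].
#' @return A data.frame of class `roh_set` with columns `sample_id`,
#'   `chrom`, `start_bp`, `end_bp`, `n_snps`, `length_bp`.
#' @export
detect_roh <- function(ds, cfg = roh_config()) {
  chroms <- unique(ds$snps$chrom)
  short <- chroms[vapply(chroms,
                         function(ch) sum(ds$snps$chrom == ch), 0L) <
                    cfg$window_snps]
  if (length(short))
    warning("chromosome(s) with fewer than ", cfg$window_snps,
            " SNPs evaluated with truncated windows: ",
            paste(short, collapse = ", "))
  out <- list()
  for (ch in chroms) {
    jj <- which(ds$snps$chrom == ch)
    bp <- ds$snps$bp[jj]
    gap_break <- which(diff(bp) > cfg$max_internal_gap_kb * 1000)
    for (i in seq_len(nrow(ds$samples))) {
      cand <- .roh_candidates(ds$calls[i, jj], cfg)
      # break candidate stretches at non-candidates and at large gaps
      brk <- c(which(diff(cand) != 0), gap_break)
      run_id <- cumsum(c(0L, as.integer(seq_len(length(cand) - 1L) %in%
                                          brk)))
      for (r in unique(run_id[cand])) {
        idx <- which(run_id == r & cand)
        len <- bp[idx[length(idx)]] - bp[idx[1]] + 1L
        if (len < cfg$min_length_kb * 1000) next
        if (len / length(idx) > cfg$min_density_kb_per_snp * 1000) next
        out[[length(out) + 1L]] <- data.frame(
          sample_id = ds$samples$sample_id[i], chrom = ch,
          start_bp = bp[idx[1]], end_bp = bp[idx[length(idx)]],
          n_snps = length(idx), length_bp = len)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(sample_id = character(), chrom = character(),
                  start_bp = integer(), end_bp = integer(),
                  n_snps = integer(), length_bp = integer())
  rownames(res) <- NULL
  class(res) <- c("roh_set", "data.frame")
  attr(res, "config") <- cfg
  res
}

#' Genomic inbreeding coefficient from ROH
#'
#' F_ROH for each animal: the summed length of its ROH divided by the
#' autosomal length covered by SNPs, L_AUTO, computed from the dataset
#' itself as the sum over chromosomes of (last SNP bp - first SNP bp + 1).
#'
#' @param segments an `roh_set` from [detect_roh()].
#' @param ds the [geno_ds()] the segments were called on.
#' @return A data.frame of class `froh_result` with columns `sample_id`,
#'   `population`, `f_roh`, `total_roh_length_bp`, `n_segments`, and
#'   attribute `l_auto_bp`.
#' @export
compute_froh <- function(segments, ds) {
  if (nrow(ds$snps) == 0L) stop("dataset has no SNPs: L_AUTO undefined")
  spans <- tapply(ds$snps$bp, ds$snps$chrom,
                  function(b) max(b) - min(b) + 1)
  l_auto <- sum(spans)
  tot <- tapply(segments$length_bp, segments$sample_id, sum)
  nseg <- tapply(segments$length_bp, segments$sample_id, length)
  ids <- ds$samples$sample_id
  total_len <- ifelse(ids %in% names(tot), as.numeric(tot[ids]), 0)
  n_segments <- ifelse(ids %in% names(nseg), as.integer(nseg[ids]), 0L)
  res <- data.frame(sample_id = ids,
                    population = ds$samples$population,
                    f_roh = total_len / l_auto,
                    total_roh_length_bp = total_len,
                    n_segments = n_segments)
  stopifnot(all(res$f_roh >= 0 & res$f_roh <= 1))
  class(res) <- c("froh_result", "data.frame")
  attr(res, "l_auto_bp") <- l_auto
  res
}

#' Compare F_ROH distributions between populations
#'
#' Wilcoxon rank-sum tests for every pairwise population comparison, with
#' Bonferroni correction across all pairs. The exact null distribution is
#' used when the smaller group has at most 12 animals and there are no
#' ties; otherwise the normal approximation with tie-corrected variance
#' (and continuity correction) is used.
#'
#' @param froh a `froh_result` from [compute_froh()] (or any data.frame
#'   with `population` and `f_roh` columns).
#' @return A data.frame of class `froh_comparison` with columns `pop_a`,
#'   `pop_b`, `statistic` (rank-sum W for pop_a), `p_raw`, `p_adjusted`,
#'   `mean_a`, `mean_b`.
#' @export
compare_froh <- function(froh) {
  pops <- unique(froh$population)
  if (length(pops) < 2L) stop("need at least 2 populations")
  combos <- utils::combn(pops, 2)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    a <- froh$f_roh[froh$population == combos[1, k]]
    b <- froh$f_roh[froh$population == combos[2, k]]
    if (length(a) < 2L || length(b) < 2L)
      stop("each population needs >= 2 animals")
    if (length(unique(c(a, b))) == 1L) {
      warning("degenerate comparison (all values equal): P = 1")
      w <- list(statistic = length(a) * length(b) / 2, p.value = 1)
    } else {
      ties <- anyDuplicated(c(a, b)) > 0L
      use_exact <- !ties && min(length(a), length(b)) <= 12L
      w <- suppressWarnings(
        stats::wilcox.test(a, b, exact = use_exact, correct = !use_exact))
    }
    data.frame(pop_a = combos[1, k], pop_b = combos[2, k],
               statistic = unname(w$statistic), p_raw = w$p.value,
               mean_a = mean(a), mean_b = mean(b))
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- pmin(1, res$p_raw * nrow(res))
  res <- res[, c("pop_a", "pop_b", "statistic", "p_raw", "p_adjusted",
                 "mean_a", "mean_b")]
  class(res) <- c("froh_comparison", "data.frame")
  res
}

#' Write ROH segments as BED-like text
#'
#' Tab-separated `chrom, start-1, end, sample_id, n_snps` (0-based
#' half-open intervals, the BED convention).
#'
#' @param segments an `roh_set`.
#' @param path output file.
#' @export
write_roh_bed <- function(segments, path) {
  utils::write.table(
    data.frame(segments$chrom, segments$start_bp - 1L, segments$end_bp,
               segments$sample_id, segments$n_snps),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
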