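#' SNP and sample quality-control configuration
#'
#' Defaults follow standard SNP-array practice for 50K bovine data: SNPs
#' with more than 10% missing calls or minor allele frequency at or below
#' 1% are removed, Hardy-Weinberg equilibrium is tested within each
#' population at an exact-test threshold of 1e-4, and samples with call
#' rate below 90% are then dropped. For LD-based effective-population-size
#' work a stricter `min_maf = 0.05` is used; for ROH/inbreeding work the
#' MAF filter is disabled (`min_maf = NULL`).
#'
#' @param max_snp_missing maximum fraction of missing calls per SNP.
#' @param min_maf SNPs with MAF `<= min_maf` are removed; `NULL` disables
#'   the MAF filter.
#' @param min_sample_call_rate minimum per-sample call rate.
#' @param hwe_p_threshold SNPs with within-population exact HWE P below
#'   this are removed; `NULL` disables.
#' @param seed integer seed used for any randomized step downstream.
#' @return A `qc_config` list.
#' @export
qc_config <- function(max_snp_missing = 0.10, min_maf = 0.01,
                      min_sample_call_rate = 0.90,
                      hwe_p_threshold = 1e-4, seed = 1L) {
  for (v in c(max_snp_missing, min_maf, min_sample_call_rate))
    if (!is.null(v) && (v < 0 || v > 1)) stop("fractions must lie in [0,1]")
  structure(list(max_snp_missing = max_snp_missing, min_maf = min_maf,
                 min_sample_call_rate = min_sample_call_rate,
                 hwe_p_threshold = hwe_p_threshold, seed = as.integer(seed)),
            class = "qc_config")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' P-value is the total probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (the standard exact-test convention). Probabilities follow the
#' Levene-Haldane distribution of heterozygote counts given allele counts.
#'
#' @param n_aa,n_ab,n_bb observed genotype counts.
#' @return Exact two-sided P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("all genotype counts are zero: HWE test undefined")
  n_a <- 2L * n_aa + n_ab   # rarer-or-not does not matter, symmetric
  if (n_a == 0L || n_a == 2L * n) return(1)   # monomorphic
  # possible heterozygote counts share the parity of n_a and satisfy
  # n_ab <= min(n_a, 2n - n_a)
  n_b <- 2L * n - n_a
  hets <- seq(n_a %% 2L, min(n_a, n_b), by = 2L)
  # log P(n_ab | n, n_a) up to a constant:
  #   n! / (naa! nab! nbb!) * 2^nab  with naa = (n_a - nab)/2 etc.
  logp <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    bb <- (n_b - h) / 2
    h * log(2) - lfactorial(aa) - lfactorial(h) - lfactorial(bb)
  }, 0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[hets == n_ab]
  # tolerance guards against ties lost to floating-point rounding
  sum(p[p <= p_obs * (1 + 1e-9)])
}

# Per-SNP allele frequency of a2 over non-missing calls; NA if all missing.
.a2_freq <- function(calls) colMeans(calls, na.rm = TRUE) / 2

# MAF per SNP.
.maf <- function(calls) {
  p <- .a2_freq(calls)
  pmin(p, 1 - p)
}

#' Apply SNP and sample quality control
#'
#' Filtering proceeds in a fixed, logged order: (1) SNP missingness,
#' (2) SNP minor allele frequency (when enabled; SNPs with MAF at or below
#' the threshold are removed), (3) within-population exact HWE (a SNP is
#' removed if it fails in any population present), then (4) per-sample
#' call rate. SNP filters therefore see all input samples, and the sample
#' filter sees only surviving SNPs.
#'
#' @param ds a [geno_ds()].
#' @param cfg a [qc_config()].
#' @return A list with elements `dataset` (the filtered [geno_ds()]) and
#'   `report` (a `qc_report` with per-rule removal counts, removed sample
#'   ids, and per-population mean observed heterozygosity on the retained
#'   data).
#' @export
apply_qc <- function(ds, cfg = qc_config()) {
  n_snp0 <- nrow(ds$snps)
  n_samp0 <- nrow(ds$samples)
  removed <- c(missingness = 0L, maf = 0L, hwe = 0L)

  miss_frac <- colMeans(is.na(ds$calls))
  keep <- miss_frac <= cfg$max_snp_missing
  removed["missingness"] <- sum(!keep)
  ds <- subset_geno(ds, snp_ids = ds$snps$snp_id[keep])

  if (!is.null(cfg$min_maf)) {
    keep <- .maf(ds$calls) > cfg$min_maf
    keep[is.na(keep)] <- FALSE
    removed["maf"] <- sum(!keep)
    ds <- subset_geno(ds, snp_ids = ds$snps$snp_id[keep])
  }

  if (!is.null(cfg$hwe_p_threshold)) {
    pops <- unique(ds$samples$population)
    fail <- rep(FALSE, nrow(ds$snps))
    for (pop in pops) {
      g <- ds$calls[.pop_rows(ds, pop), , drop = FALSE]
      n_aa <- colSums(g == 0L, na.rm = TRUE)
      n_ab <- colSums(g == 1L, na.rm = TRUE)
      n_bb <- colSums(g == 2L, na.rm = TRUE)
      tot <- n_aa + n_ab + n_bb
      pv <- rep(1, nrow(ds$snps))
      for (j in which(tot > 0))
        pv[j] <- hwe_exact_test(n_aa[j], n_ab[j], n_bb[j])
      fail <- fail | pv < cfg$hwe_p_threshold
    }
    removed["hwe"] <- sum(fail)
    ds <- subset_geno(ds, snp_ids = ds$snps$snp_id[!fail])
  }

  call_rate <- rowMeans(!is.na(ds$calls))
  drop_samp <- ds$samples$sample_id[call_rate < cfg$min_sample_call_rate]
  ds <- subset_geno(ds,
                    sample_ids = setdiff(ds$samples$sample_id, drop_samp))

  if (nrow(ds$snps) == 0L || nrow(ds$samples) == 0L)
    stop("no data survive QC")

  ho <- vapply(unique(ds$samples$population),
               function(p) observed_heterozygosity(ds, p), 0)
  report <- structure(list(
    snps_removed_by_rule = removed,
    samples_removed = drop_samp,
    snps_retained = nrow(ds$snps),
    snps_input = n_snp0,
    samples_input = n_samp0,
    ho_by_population = ho,
    config = cfg), class = "qc_report")
  stopifnot(report$snps_retained + sum(removed) == n_snp0)
  list(dataset = ds, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP/sample QC report\n")
  cat("  SNPs: ", x$snps_input, " in, ", x$snps_retained, " retained (",
      "missingness ", x$snps_removed_by_rule[["missingness"]],
      ", MAF ", x$snps_removed_by_rule[["maf"]],
      ", HWE ", x$snps_removed_by_rule[["hwe"]], " removed)\n", sep = "")
  cat("  samples removed (call rate): ",
      if (length(x$samples_removed))
        paste(x$samples_removed, collapse = ", ") else "none", "\n",
      sep = "")
  cat("  mean observed heterozygosity by population:\n")
  for (p in names(x$ho_by_population))
    cat(sprintf("    %-10s %.4f\n", p, x$ho_by_population[[p]]))
  invisible(x)
}

#' Mean observed heterozygosity of a population
#'
#' Mean over SNPs of the fraction of heterozygous calls among non-missing
#' calls within the population; SNPs with no non-missing call in the
#' population are excluded from the mean.
#'
#' @param ds a [geno_ds()].
#' @param population population code present in `ds$samples$population`.
#' @return Mean observed heterozygosity in \[0, 1\].
#' @export
observed_heterozygosity <- function(ds, population) {
  g <- ds$calls[.pop_rows(ds, population), , drop = FALSE]
  het <- colSums(g == 1L, na.rm = TRUE)
  n <- colSums(!is.na(g))
  mean((het / n)[n > 0])
}
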