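#' Configuration for LD-based effective population size estimation
#'
#' Historical N_e is read off the decay of linkage disequilibrium with
#' recombination distance: the expected adjusted LD at recombination rate
#' c reflects the effective size about 1/(2c) generations ago. Physical
#' distance is mapped to recombination rate linearly (`cm_per_mb`, default
#' 1 cM/Mb, the standard cattle-genome average), pairs are binned by
#' physical distance, and each bin yields one (t, N_T) point via
#' \deqn{N_T = (4 f(c_t))^{-1} (E[r^2_{adj} | c_t]^{-1} - \alpha)}
#' with `t = 1/(2 f(c_t))` and mutation correction `alpha` (default 1).
#'
#' @param maf_min minimum minor allele frequency for SNPs entering LD
#'   pairs (default 0.05).
#' @param alpha mutation correction; 1 is the recommended default.
#' @param dist_bins numeric vector of bin edges in bp (default 30
#'   log-spaced bins from 50 kb to 4 Mb, spanning roughly 12 to 1000
#'   generations ago at 1 cM/Mb).
#' @param cm_per_mb linear physical-to-genetic map rate.
#' @param min_pairs_per_bin bins with fewer pairs are dropped.
#' @param min_samples_per_pair SNP pairs with fewer mutually non-missing
#'   samples are skipped.
#' @return An `ne_config` list.
#' @export
ne_config <- function(maf_min = 0.05, alpha = 1,
                      dist_bins = exp(seq(log(5e4), log(4e6),
                                          length.out = 31)),
                      cm_per_mb = 1, min_pairs_per_bin = 50,
                      min_samples_per_pair = 10) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (is.unsorted(dist_bins, strictly = TRUE))
    stop("dist_bins edges must be strictly ascending")
  structure(list(maf_min = maf_min, alpha = alpha, dist_bins = dist_bins,
                 cm_per_mb = cm_per_mb,
                 min_pairs_per_bin = min_pairs_per_bin,
                 min_samples_per_pair = min_samples_per_pair),
            class = "ne_config")
}

#' Pairwise adjusted LD within a population
#'
#' For every within-chromosome SNP pair whose physical distance falls in
#' the configured bin range, computes r^2 as the squared Pearson
#' correlation of 0/1/2 genotype dosages over mutually non-missing
#' samples (the unphased, genotype-based LD measure), then subtracts the
#' chromosome-sample-size expectation: `r2_adj = r^2 - 1/n`, floored at 0.
#' SNPs failing the MAF filter, pairs with undefined correlation
#' (monomorphic member) and pairs with fewer than
#' `min_samples_per_pair` usable samples are skipped.
#'
#' @param ds a [geno_ds()].
#' @param population population code.
#' @param cfg an [ne_config()].
#' @return data.frame with columns `snp_i`, `snp_j`, `chrom`,
#'   `distance_bp`, `r2_adj`, `n`; skipped-pair counts in attribute
#'   `skipped`.
#' @export
pairwise_r2 <- function(ds, population, cfg = ne_config()) {
  rows <- .pop_rows(ds, population)
  g <- ds$calls[rows, , drop = FALSE]
  maf <- .maf(g)
  keep <- !is.na(maf) & maf >= cfg$maf_min
  g <- g[, keep, drop = FALSE]
  snps <- ds$snps[keep, , drop = FALSE]
  dmin <- min(cfg$dist_bins)
  dmax <- max(cfg$dist_bins)
  skipped <- c(low_n = 0L, degenerate = 0L)
  out <- list()
  for (ch in unique(snps$chrom)) {
    jj <- which(snps$chrom == ch)
    bp <- snps$bp[jj]
    x <- g[, jj, drop = FALSE]
    obs <- !is.na(x)
    nj <- length(jj)
    for (a in seq_len(max(0L, nj - 1L))) {
      lo <- max(a + 1L, findInterval(bp[a] + dmin - 0.5, bp) + 1L)
      hi <- min(nj, findInterval(bp[a] + dmax + 0.5, bp))
      if (lo > hi) next
      bb <- lo:hi
      d <- bp[bb] - bp[a]
      n_pair <- colSums(obs[, a] & obs[, bb, drop = FALSE])
      r <- suppressWarnings(
        stats::cor(x[, a], x[, bb, drop = FALSE],
                   use = "pairwise.complete.obs"))[1, ]
      bad_n <- n_pair < cfg$min_samples_per_pair
      bad_r <- is.na(r)
      skipped["low_n"] <- skipped["low_n"] + sum(bad_n)
      skipped["degenerate"] <- skipped["degenerate"] + sum(!bad_n & bad_r)
      ok <- !bad_n & !bad_r
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.frame(
        snp_i = snps$snp_id[jj[a]], snp_j = snps$snp_id[jj[bb[ok]]],
        chrom = ch, distance_bp = d[ok],
        r2_adj = pmax(0, r[ok]^2 - 1 / n_pair[ok]), n = n_pair[ok])
    }
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(snp_i = character(), snp_j = character(),
                  chrom = character(), distance_bp = numeric(),
                  r2_adj = numeric(), n = integer())
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Bin LD pairs by physical distance
#'
#' Assigns each pair to the distance bin containing it, takes the
#' arithmetic mean of adjusted r^2 per bin, and converts the bin midpoint
#' to a recombination rate in Morgans via the linear map:
#' `c_t = midpoint_bp * cm_per_mb * 1e-8`. Bins with fewer than
#' `min_pairs_per_bin` pairs are dropped with a warning.
#'
#' @param pairs output of [pairwise_r2()].
#' @param cfg an [ne_config()].
#' @return data.frame with columns `c_t`, `mean_r2_adj`, `n_pairs`,
#'   `midpoint_bp`.
#' @export
bin_ld <- function(pairs, cfg = ne_config()) {
  if (nrow(pairs) == 0L) stop("no SNP pairs to bin")
  edges <- cfg$dist_bins
  bin <- findInterval(pairs$distance_bp, edges, rightmost.closed = TRUE)
  inside <- bin >= 1L & bin <= length(edges) - 1L
  bin <- bin[inside]
  r2 <- pairs$r2_adj[inside]
  mid <- (edges[-length(edges)] + edges[-1]) / 2
  n_pairs <- tabulate(bin, nbins = length(edges) - 1L)
  mean_r2 <- vapply(seq_along(mid),
                    function(b) if (n_pairs[b]) mean(r2[bin == b]) else NA_real_,
                    0)
  keep <- n_pairs >= cfg$min_pairs_per_bin
  if (any(!keep & n_pairs > 0))
    warning(sum(!keep & n_pairs > 0), " bin(s) dropped (fewer than ",
            cfg$min_pairs_per_bin, " pairs)")
  data.frame(c_t = mid[keep] * cfg$cm_per_mb * 1e-8,
             mean_r2_adj = mean_r2[keep], n_pairs = n_pairs[keep],
             midpoint_bp = mid[keep])
}

#' Effective population size trajectory from binned LD
#'
#' Evaluates, per distance bin,
#' `N_T = (1 / (4 c_t)) * (1 / mean_r2_adj - alpha)` at
#' `t = 1 / (2 c_t)` generations ago. Bins whose mean adjusted r^2 is
#' non-positive are skipped with a warning; negative N_T (adjusted LD
#' below the mutation correction) is floored at 0 with a warning.
#'
#' @param bins output of [bin_ld()].
#' @param cfg an [ne_config()].
#' @param generation_interval_years optional scalar or length-2 range for
#'   calendar conversion (stored, not applied).
#' @return data.frame of class `ne_trajectory`, ascending in `t`, with
#'   columns `t`, `n_t`, `c_t`, `mean_r2_adj`, `n_pairs`.
#' @export
estimate_ne <- function(bins, cfg = ne_config(),
                        generation_interval_years = c(4, 6)) {
  usable <- bins$mean_r2_adj > 0
  if (any(!usable))
    warning(sum(!usable), " bin(s) skipped (non-positive mean r2_adj)")
  b <- bins[usable, , drop = FALSE]
  n_t <- (1 / (4 * b$c_t)) * (1 / b$mean_r2_adj - cfg$alpha)
  if (any(n_t < 0)) {
    warning(sum(n_t < 0), " negative N_T value(s) floored at 0")
    n_t <- pmax(0, n_t)
  }
  res <- data.frame(t = 1 / (2 * b$c_t), n_t = n_t, c_t = b$c_t,
                    mean_r2_adj = b$mean_r2_adj, n_pairs = b$n_pairs)
  res <- res[order(res$t), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ne_trajectory", "data.frame")
  attr(res, "generation_interval_years") <- generation_interval_years
  res
}

#' One-call N_e trajectory for a population
#'
#' Convenience wrapper: [pairwise_r2()] then [bin_ld()] then
#' [estimate_ne()].
#'
#' @inheritParams pairwise_r2
#' @export
ne_trajectory <- function(ds, population, cfg = ne_config()) {
  estimate_ne(bin_ld(pairwise_r2(ds, population, cfg), cfg), cfg)
}

#' @export
plot.ne_trajectory <- function(x, ...) {
  graphics::plot(x$t, x$n_t, log = "xy", type = "b", pch = 16,
                 xlab = "generations ago", ylab = expression(N[e]), ...)
  invisible(x)
}
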