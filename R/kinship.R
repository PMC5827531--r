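#' Pairwise identity-by-state matrix
#'
#' Mean per-SNP IBS sharing `1 - |g_i - g_j| / 2` over mutually non-missing
#' SNPs, for every pair of samples. Duplicate samples score 1; opposite
#' homozygotes at every SNP score 0. Invariant under swapping the allele
#' coding (0 <-> 2) of both samples.
#'
#' @param ds a [geno_ds()].
#' @return A `kinship_result` with a symmetric `ibs` matrix (diagonal 1;
#'   `NA` where a pair shares no genotyped SNP, with such pairs listed in
#'   `no_overlap_pairs`).
#' @export
ibs_matrix <- function(ds) {
  n <- nrow(ds$samples)
  if (n < 2L) stop("need at least 2 samples")
  g <- ds$calls
  obs <- !is.na(g)
  g0 <- g
  g0[!obs] <- 0L
  # sum over shared SNPs of |gi - gj| via expansion into indicator matrices:
  # |gi-gj| = sum_k,l |k-l| * 1{gi=k} * 1{gj=l}
  ind <- lapply(0:2, function(k) (g0 == k & obs) * 1)
  n_shared <- tcrossprod(obs * 1)
  absdiff <- matrix(0, n, n)
  for (k in 0:2) for (l in 0:2) if (k != l)
    absdiff <- absdiff + abs(k - l) * tcrossprod(ind[[k + 1]], ind[[l + 1]])
  ibs <- 1 - absdiff / (2 * n_shared)
  ibs[n_shared == 0] <- NA
  diag(ibs) <- 1
  dimnames(ibs) <- list(ds$samples$sample_id, ds$samples$sample_id)
  no_overlap <- which(n_shared == 0 & upper.tri(n_shared), arr.ind = TRUE)
  structure(list(
    ibs = ibs,
    no_overlap_pairs = data.frame(
      id1 = ds$samples$sample_id[no_overlap[, 1]],
      id2 = ds$samples$sample_id[no_overlap[, 2]])),
    class = "kinship_result")
}

#' @export
print.kinship_result <- function(x, ...) {
  if (!is.null(x$ibs)) {
    cat("IBS matrix over", nrow(x$ibs), "samples; mean off-diagonal IBS",
        sprintf("%.4f\n", mean(x$ibs[upper.tri(x$ibs)], na.rm = TRUE)))
  }
  if (!is.null(x$pairs)) {
    cat(nrow(x$pairs), "pair(s) compatible with parent-offspring",
        "(opposite-homozygote rate <= allowance)\n")
    if (nrow(x$pairs)) print(x$pairs, row.names = FALSE)
  }
  invisible(x)
}

#' Detect parent-offspring pairs by genomic non-exclusion
#'
#' A true parent and offspring can never be opposite homozygotes (0 vs 2)
#' at a biallelic locus, barring genotyping error. Pairs whose
#' opposite-homozygote rate over mutually non-missing SNPs is at or below
#' `error_allowance` are flagged as compatible with a parent-offspring
#' relationship. The default allowance of 0.005 tolerates very low-level
#' genotyping error while remaining far below the rate expected even for
#' full sibs or grandparent-grandchild pairs on array-scale SNP sets.
#'
#' @param ds a [geno_ds()].
#' @param error_allowance maximum opposite-homozygote rate for a flagged
#'   pair.
#' @return A `kinship_result` with `pairs` (data.frame `id1`, `id2`,
#'   `oh_rate`, `n_shared`) and the full `oh_rate` matrix.
#' @export
detect_parent_offspring <- function(ds, error_allowance = 0.005) {
  n <- nrow(ds$samples)
  if (n < 2L) stop("need at least 2 samples")
  g <- ds$calls
  obs <- !is.na(g)
  hom0 <- (g == 0L & obs) * 1
  hom2 <- (g == 2L & obs) * 1
  opp <- tcrossprod(hom0, hom2)
  opp <- opp + t(opp)
  n_shared <- tcrossprod(obs * 1)
  rate <- opp / n_shared
  rate[n_shared == 0] <- NA
  diag(rate) <- NA
  dimnames(rate) <- list(ds$samples$sample_id, ds$samples$sample_id)
  hit <- which(rate <= error_allowance & upper.tri(rate), arr.ind = TRUE)
  pairs <- data.frame(
    id1 = ds$samples$sample_id[hit[, 1]],
    id2 = ds$samples$sample_id[hit[, 2]],
    oh_rate = rate[hit],
    n_shared = n_shared[hit])
  structure(list(pairs = pairs, oh_rate = rate,
                 error_allowance = error_allowance),
            class = "kinship_result")
}

#' Remove one member of each detected pair
#'
#' Exactly one animal of each flagged pair is removed. Chains (a sample
#' appearing in several pairs) are resolved greedily: while any pair
#' remains, the sample with the highest pair degree is removed (seeded
#' uniform choice among ties; for degree-1 disjoint pairs this is a random
#' member), and remaining pairs are re-evaluated. Reproducible under
#' `seed`.
#'
#' @param ds a [geno_ds()].
#' @param pairs data.frame with columns `id1`, `id2` (e.g. from
#'   [detect_parent_offspring()]).
#' @param seed integer seed.
#' @return The [geno_ds()] with the chosen samples removed; removed ids in
#'   attribute `removed`.
#' @export
remove_pair_members <- function(ds, pairs, seed = 1L) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(ds)
  stopifnot(all(c(pairs$id1, pairs$id2) %in% ds$samples$sample_id))
  edges <- pairs[, c("id1", "id2")]
  removed <- character(0)
  set.seed(seed)
  while (nrow(edges) > 0L) {
    deg <- table(c(edges$id1, edges$id2))
    top <- names(deg)[deg == max(deg)]
    pick <- top[sample.int(length(top), 1L)]
    removed <- c(removed, pick)
    edges <- edges[edges$id1 != pick & edges$id2 != pick, , drop = FALSE]
  }
  out <- subset_geno(ds,
                     sample_ids = setdiff(ds$samples$sample_id, removed))
  attr(out, "removed") <- removed
  out
}
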