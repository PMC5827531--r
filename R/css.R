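#' Configuration for the composite selection scan
#'
#' Defines the test-versus-reference contrast and the EHH integration
#' rules. The reference pool is drawn reproducibly as `per_breed` animals
#' from each reference population. EHH decay curves are integrated from
#' each core SNP until homozygosity falls below `ehh_decay_cutoff`, the
#' extension exceeds `ehh_max_extension_bp`, or an inter-SNP gap exceeds
#' `ehh_gap_limit_bp`.
#'
#' @param test_pop population code of the test population.
#' @param ref_pops character vector of reference population codes.
#' @param per_breed animals drawn per reference population.
#' @param seed integer seed for the reference draw.
#' @param ehh_decay_cutoff EHH level at which integration stops.
#' @param ehh_max_extension_bp maximum one-sided extension (default 2 Mb).
#' @param ehh_gap_limit_bp gap that truncates integration (default 200 kb).
#' @return A `contrast_config` list.
#' @export
contrast_config <- function(test_pop, ref_pops, per_breed = 6, seed = 1L,
                            ehh_decay_cutoff = 0.05,
                            ehh_max_extension_bp = 2e6,
                            ehh_gap_limit_bp = 2e5) {
  if (test_pop %in% ref_pops)
    stop("test population must be disjoint from the reference pool")
  structure(list(test_pop = test_pop, ref_pops = ref_pops,
                 per_breed = as.integer(per_breed), seed = as.integer(seed),
                 ehh_decay_cutoff = ehh_decay_cutoff,
                 ehh_max_extension_bp = ehh_max_extension_bp,
                 ehh_gap_limit_bp = ehh_gap_limit_bp),
            class = "contrast_config")
}

#' Draw the reference pool
#'
#' Seeded draw of `per_breed` animals from each reference population
#' (all animals of a population if it has fewer).
#'
#' @param ds a [geno_ds()].
#' @param cfg a [contrast_config()].
#' @return Character vector of sample ids.
#' @export
draw_ref_pool <- function(ds, cfg) {
  set.seed(cfg$seed)
  unlist(lapply(cfg$ref_pops, function(p) {
    ids <- ds$samples$sample_id[ds$samples$population == p]
    if (!length(ids)) stop("reference population not present: ", p)
    if (length(ids) <= cfg$per_breed) ids
    else sample(ids, cfg$per_breed)
  }), use.names = FALSE)
}

# Resolve a group spec (population code(s) or sample ids) to row indices.
.group_rows <- function(ds, group) {
  if (all(group %in% ds$samples$population))
    which(ds$samples$population %in% group)
  else if (all(group %in% ds$samples$sample_id))
    which(ds$samples$sample_id %in% group)
  else stop("group is neither a set of population codes nor of sample ids")
}

# Genotype summary per SNP for a group: non-missing n, a2 frequency p,
# observed heterozygote frequency h.
.group_freqs <- function(g) {
  n <- colSums(!is.na(g))
  list(n = n, p = colMeans(g, na.rm = TRUE) / 2,
       h = colSums(g == 1L, na.rm = TRUE) / n)
}

#' Per-SNP Weir-Cockerham F_ST
#'
#' Two-population Weir-Cockerham theta per SNP from genotype counts,
#' using the variance components a (among populations), b (among
#' individuals within populations) and c (within individuals). SNPs
#' monomorphic in the pooled sample get theta 0 with a flag; SNPs with
#' fewer than 2 non-missing calls in either group are excluded (`NA`).
#'
#' @param ds a [geno_ds()].
#' @param test,ref population code(s) or sample-id vectors; must not
#'   overlap.
#' @return data.frame `snp_id`, `fst`, `flag`.
#' @export
fst_per_snp <- function(ds, test, ref) {
  gi <- .group_freqs(ds$calls[.group_rows(ds, test), , drop = FALSE])
  gj <- .group_freqs(ds$calls[.group_rows(ds, ref), , drop = FALSE])
  n1 <- gi$n; n2 <- gj$n
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * gi$p + n2 * gj$p) / (r * nbar)
  s2 <- (n1 * (gi$p - pbar)^2 + n2 * (gj$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * gi$h + n2 * gj$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) /
       (4 * nbar))
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  flag <- rep("", length(theta))
  mono <- !is.na(pbar) & (pbar == 0 | pbar == 1)
  theta[mono] <- 0
  flag[mono] <- "monomorphic"
  low <- n1 < 2L | n2 < 2L
  theta[low] <- NA
  flag[low] <- "insufficient_calls"
  data.frame(snp_id = ds$snps$snp_id, fst = theta, flag = flag)
}

#' Per-SNP allele-frequency change
#'
#' `|p_test - p_ref|` for the a2 allele: the absolute change in selected
#' allele frequency. The ancestral state is unknown on a SNP array, so
#' the absolute change is used (larger = stronger evidence).
#'
#' @inheritParams fst_per_snp
#' @return data.frame `snp_id`, `dsaf`, `flag`.
#' @export
delta_saf <- function(ds, test, ref) {
  gi <- .group_freqs(ds$calls[.group_rows(ds, test), , drop = FALSE])
  gj <- .group_freqs(ds$calls[.group_rows(ds, ref), , drop = FALSE])
  d <- abs(gi$p - gj$p)
  flag <- ifelse(is.na(d), "all_missing_in_group", "")
  data.frame(snp_id = ds$snps$snp_id, dsaf = d, flag = flag)
}

# EHH decay from a core SNP in one direction over one chromosome.
# H: haplotype matrix (haplotypes x SNPs on this chromosome), bp sorted
# ascending. Returns the trapezoidal integral of population-level EHH
# (probability two random haplotypes are identical over [core, x]) in bp.
.ihh_one_side <- function(H, bp, core, step, cfg) {
  m <- nrow(H)
  if (m < 2L) return(0)
  grp <- H[, core] + 1L
  ehh_prev <- .hom_prob(grp, m)
  if (ehh_prev < cfg$ehh_decay_cutoff) return(0)
  pos_prev <- bp[core]
  ihh <- 0
  j <- core + step
  while (j >= 1L && j <= length(bp)) {
    gap <- abs(bp[j] - pos_prev)
    if (gap > cfg$ehh_gap_limit_bp) break
    if (abs(bp[j] - bp[core]) > cfg$ehh_max_extension_bp) break
    grp <- grp * 2L + H[, j]
    grp <- match(grp, unique(grp))
    ehh <- .hom_prob(grp, m)
    ihh <- ihh + (ehh_prev + ehh) / 2 * gap
    if (ehh < cfg$ehh_decay_cutoff) return(ihh)
    ehh_prev <- ehh
    pos_prev <- bp[j]
    j <- j + step
  }
  ihh
}

.hom_prob <- function(grp, m) {
  cnt <- tabulate(grp)
  sum(cnt * (cnt - 1)) / (m * (m - 1))
}

#' Cross-population extended haplotype homozygosity scan
#'
#' For every SNP, computes the integrated EHH (trapezoidal integral over
#' physical distance of the probability that two random haplotypes are
#' identical from the core outward, both directions) in the test and
#' reference haplotype sets, takes `ln(iHH_test / iHH_ref)`, and
#' z-normalizes the log-ratios genome-wide. Population-level EHH (all
#' haplotypes, not stratified by core allele) is used so every SNP yields
#' a value. Requires phased haplotypes: simulator output is phased; real
#' unphased data must be phased externally first.
#'
#' @param hap_test,hap_ref 0/1 haplotype matrices (haplotypes in rows),
#'   columns aligned with `snps`.
#' @param snps SNP map data.frame (`chrom`, `snp_id`, `bp`),
#'   position-sorted.
#' @param cfg a [contrast_config()].
#' @return data.frame `snp_id`, `xpehh_raw`, `xpehh` (normalized),
#'   `flag` (`"zero_ihh"` where a side integrates to 0; such SNPs get
#'   `NA`).
#' @export
xpehh_scan <- function(hap_test, hap_ref, snps, cfg) {
  stopifnot(ncol(hap_test) == nrow(snps), ncol(hap_ref) == nrow(snps))
  raw <- rep(NA_real_, nrow(snps))
  flag <- rep("", nrow(snps))
  for (ch in unique(snps$chrom)) {
    jj <- which(snps$chrom == ch)
    bp <- snps$bp[jj]
    Ht <- hap_test[, jj, drop = FALSE]
    Hr <- hap_ref[, jj, drop = FALSE]
    for (k in seq_along(jj)) {
      it <- .ihh_one_side(Ht, bp, k, -1L, cfg) +
        .ihh_one_side(Ht, bp, k, +1L, cfg)
      ir <- .ihh_one_side(Hr, bp, k, -1L, cfg) +
        .ihh_one_side(Hr, bp, k, +1L, cfg)
      if (ir == 0 || it == 0) flag[jj[k]] <- "zero_ihh"
      else raw[jj[k]] <- log(it / ir)
    }
  }
  z <- (raw - mean(raw, na.rm = TRUE)) / stats::sd(raw, na.rm = TRUE)
  data.frame(snp_id = snps$snp_id, xpehh_raw = raw, xpehh = z,
             flag = flag)
}

#' Composite selection signal from constituent statistics
#'
#' Rank-based combination: each constituent test's values are converted
#' to fractional ranks `rank / (n + 1)` (average ranks for ties), probit
#' transformed, averaged across the k tests, and the mean z-score is
#' referred to its null Normal(0, 1/sqrt(k)) distribution;
#' `CSS = -log10(p)` of the upper tail. Equal weights across tests.
#'
#' @param stats numeric matrix or data.frame, SNPs in rows, one column
#'   per constituent test (larger values = stronger selection evidence).
#'   Rows with any `NA` are excluded (`NA` CSS).
#' @return Numeric vector of CSS scores (>= 0 up to floating point; `NA`
#'   for excluded rows).
#' @export
composite_selection_signal <- function(stats) {
  stats <- as.matrix(stats)
  k <- ncol(stats)
  if (k == 0L) stop("no constituent tests supplied")
  complete <- stats::complete.cases(stats)
  n <- sum(complete)
  z <- apply(stats[complete, , drop = FALSE], 2,
             function(x) stats::qnorm(rank(x, ties.method = "average") /
                                        (n + 1)))
  zbar <- rowMeans(z)
  p <- 1 - stats::pnorm(zbar * sqrt(k))
  out <- rep(NA_real_, nrow(stats))
  out[complete] <- -log10(p)
  out
}

#' Smooth CSS in 1 Mb windows
#'
#' Per SNP, the mean CSS of all SNPs in its non-overlapping 1 Mb
#' chromosome window (windows tiled from position 1).
#'
#' @param chrom,bp,css parallel vectors.
#' @param window_bp window size (default 1 Mb).
#' @return Numeric vector of smoothed CSS.
#' @export
smooth_css <- function(chrom, bp, css, window_bp = 1e6) {
  win <- paste(chrom, (bp - 1) %/% window_bp)
  stats::ave(css, win, FUN = function(v) mean(v, na.rm = TRUE))
}

#' Call significant selection peaks
#'
#' A signal is significant when at least one SNP in the genome-wide top
#' `peak_fraction` (0.1%) of CSS scores is flanked by at least
#' `min_flank` SNPs from the top `flank_fraction` (1%) set within
#' `flank_bp` of it. Qualifying top-tier SNPs whose flanking windows
#' overlap are merged into one peak per contiguous region. Threshold
#' cutoffs are inclusive of ties. By default the rule is applied to the
#' raw CSS scores; set `use_smoothed = TRUE` to apply it to the 1 Mb
#' window means instead (window means are shared by neighbouring SNPs,
#' which makes the flanking rule much more permissive).
#'
#' @param scan data.frame with columns `chrom`, `bp`, `snp_id`, `css`
#'   and (if `use_smoothed`) `css_smoothed`.
#' @param peak_fraction,flank_fraction top fractions defining the two
#'   SNP sets.
#' @param flank_bp flanking distance (default 1 Mb).
#' @param min_flank minimum number of flanking top-tier SNPs.
#' @param use_smoothed apply the rule to smoothed CSS.
#' @return data.frame of class `selection_peaks`: `chrom`, `peak_snp`,
#'   `peak_bp`, `peak_css`, `flank_count`, `start_bp`, `end_bp`,
#'   `gene_window_start`, `gene_window_end` (peak +/- 1 Mb).
#' @export
call_peaks <- function(scan, peak_fraction = 0.001, flank_fraction = 0.01,
                       flank_bp = 1e6, min_flank = 5,
                       use_smoothed = FALSE) {
  val <- if (use_smoothed) scan$css_smoothed else scan$css
  ok <- !is.na(val)
  n <- sum(ok)
  if (n < 1000L)
    stop("fewer than 1000 scored SNPs: top-fraction thresholds degenerate")
  sorted <- sort(val[ok], decreasing = TRUE)
  thr_peak <- sorted[max(1L, ceiling(peak_fraction * n))]
  thr_flank <- sorted[max(1L, ceiling(flank_fraction * n))]
  is_peak <- ok & val >= thr_peak
  is_flank <- ok & val >= thr_flank
  qual <- which(is_peak)
  flank_count <- integer(length(qual))
  keep <- logical(length(qual))
  for (i in seq_along(qual)) {
    j <- qual[i]
    near <- which(is_flank & scan$chrom == scan$chrom[j] &
                    abs(scan$bp - scan$bp[j]) <= flank_bp)
    flank_count[i] <- length(setdiff(near, j))
    keep[i] <- flank_count[i] >= min_flank
  }
  qual <- qual[keep]
  flank_count <- flank_count[keep]
  if (!length(qual)) {
    res <- data.frame(chrom = character(), peak_snp = character(),
                      peak_bp = integer(), peak_css = numeric(),
                      flank_count = integer(), start_bp = integer(),
                      end_bp = integer(), gene_window_start = numeric(),
                      gene_window_end = numeric())
    class(res) <- c("selection_peaks", "data.frame")
    return(res)
  }
  o <- order(scan$chrom[qual], scan$bp[qual])
  qual <- qual[o]
  flank_count <- flank_count[o]
  new_region <- c(TRUE, scan$chrom[qual[-1]] !=
                    scan$chrom[qual[-length(qual)]] |
                    diff(scan$bp[qual]) > 2 * flank_bp)
  region <- cumsum(new_region)
  rows <- lapply(split(seq_along(qual), region), function(ii) {
    jj <- qual[ii]
    top <- jj[which.max(val[jj])]
    data.frame(chrom = scan$chrom[top], peak_snp = scan$snp_id[top],
               peak_bp = scan$bp[top], peak_css = val[top],
               flank_count = max(flank_count[ii]),
               start_bp = min(scan$bp[jj]), end_bp = max(scan$bp[jj]),
               gene_window_start = pmax(1, scan$bp[top] - 1e6),
               gene_window_end = scan$bp[top] + 1e6)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("selection_peaks", "data.frame")
  res
}

#' Location of the maximal smoothed CSS signal
#'
#' The maximal smoothed CSS is a window-level value shared by every SNP
#' of its 1 Mb window, so the signal's location is reported as the
#' constituent SNP with the highest raw CSS within the maximal window.
#'
#' @param tab per-SNP scan table with columns `chrom`, `bp`, `snp_id`,
#'   `css`, `css_smoothed` (e.g. `selection_scan(...)$table`).
#' @return One-row data.frame `chrom`, `bp`, `snp_id`, `css`,
#'   `css_smoothed`.
#' @export
peak_location <- function(tab) {
  top <- which(tab$css_smoothed == max(tab$css_smoothed, na.rm = TRUE))
  best <- top[which.max(tab$css[top])]
  tab[best, c("chrom", "bp", "snp_id", "css", "css_smoothed")]
}

#' Full composite selection scan
#'
#' Draws the reference pool, computes per-SNP F_ST, allele-frequency
#' change and (when phased haplotypes are available) XP-EHH, combines
#' them into the CSS, smooths in 1 Mb windows, and calls peaks. SNPs
#' missing any constituent value are excluded with a reason.
#'
#' @param ds a [geno_ds()].
#' @param cfg a [contrast_config()].
#' @param haplotypes optional phased 0/1 haplotype matrix (2 rows per
#'   sample, in sample order; e.g. `sim_output$haplotypes`), columns
#'   aligned with `ds$snps`. Without it the CSS combines F_ST and
#'   allele-frequency change only.
#' @param ... passed to [call_peaks()].
#' @return A `selection_scan` object: list with `table` (per-SNP
#'   statistics), `peaks`, `excluded` (SNP ids and reasons), `ref_ids`,
#'   `config`.
#' @export
selection_scan <- function(ds, cfg, haplotypes = NULL, ...) {
  ref_ids <- draw_ref_pool(ds, cfg)
  test_ids <- ds$samples$sample_id[ds$samples$population == cfg$test_pop]
  if (!length(test_ids)) stop("test population not present: ", cfg$test_pop)
  fst <- fst_per_snp(ds, test_ids, ref_ids)
  dsaf <- delta_saf(ds, test_ids, ref_ids)
  tab <- data.frame(snp_id = ds$snps$snp_id, chrom = ds$snps$chrom,
                    bp = ds$snps$bp, fst = fst$fst, dsaf = dsaf$dsaf)
  if (!is.null(haplotypes)) {
    hap_rows <- function(ids) {
      i <- match(ids, ds$samples$sample_id)
      sort(c(2L * i - 1L, 2L * i))
    }
    xp <- xpehh_scan(haplotypes[hap_rows(test_ids), , drop = FALSE],
                     haplotypes[hap_rows(ref_ids), , drop = FALSE],
                     ds$snps, cfg)
    tab$xpehh <- xp$xpehh
  }
  consts <- tab[, setdiff(names(tab), c("snp_id", "chrom", "bp")),
                drop = FALSE]
  tab$css <- composite_selection_signal(consts)
  tab$css_smoothed <- smooth_css(tab$chrom, tab$bp, tab$css)
  excluded <- data.frame(
    snp_id = tab$snp_id[is.na(tab$css)],
    reason = apply(is.na(consts[is.na(tab$css), , drop = FALSE]), 1,
                   function(m) paste(names(consts)[m], collapse = ",")))
  peaks <- tryCatch(call_peaks(tab[!is.na(tab$css), , drop = FALSE], ...),
                    error = function(e) {
                      warning("peak calling skipped: ",
                              conditionMessage(e))
                      NULL
                    })
  structure(list(table = tab, peaks = peaks, excluded = excluded,
                 ref_ids = ref_ids, config = cfg),
            class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  cat("Composite selection scan:", nrow(x$table), "SNPs,",
      nrow(x$excluded), "excluded;",
      if (is.null(x$peaks)) "peaks not called" else
        paste(nrow(x$peaks), "significant peak(s)"), "\n")
  if (!is.null(x$peaks) && nrow(x$peaks))
    print(as.data.frame(x$peaks), row.names = FALSE)
  invisible(x)
}

#' @export
plot.selection_scan <- function(x, smoothed = TRUE, ...) {
  tab <- x$table
  chrom_key <- suppressWarnings(as.numeric(tab$chrom))
  if (anyNA(chrom_key)) chrom_key <- as.numeric(factor(tab$chrom))
  offs <- c(0, cumsum(tapply(tab$bp, chrom_key, max)))
  pos <- tab$bp + offs[chrom_key]
  y <- if (smoothed) tab$css_smoothed else tab$css
  graphics::plot(pos, y, pch = 16, cex = 0.4,
                 col = chrom_key %% 2 + 1,
                 xlab = "genome position (bp)",
                 ylab = if (smoothed) "smoothed CSS" else "CSS", ...)
  invisible(x)
}
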