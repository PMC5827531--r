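# Fixture builders (all generated in code; no files on disk).

# Random small genotype dataset, optionally with missing calls.
rand_ds <- function(seed, n_samples = 6, n_snps = 50, n_chrom = 2,
                    missing_rate = 0.02, span_bp = 5e6) {
  set.seed(seed)
  chrom <- sort(sample(as.character(seq_len(n_chrom)), n_snps,
                       replace = TRUE))
  bp <- unlist(lapply(unique(chrom), function(ch)
    sort(sample.int(span_bp, sum(chrom == ch)))))
  calls <- matrix(sample(0:2, n_samples * n_snps, replace = TRUE),
                  n_samples)
  calls[matrix(runif(length(calls)) < missing_rate, n_samples)] <- NA
  geno_ds(calls,
          data.frame(chrom = chrom, snp_id = paste0("s", seq_len(n_snps)),
                     cm = 0, bp = bp, a1 = "A", a2 = "B"),
          data.frame(sample_id = paste0("ind", seq_len(n_samples)),
                     population = rep(c("P1", "P2"),
                                      length.out = n_samples),
                     sex = NA_integer_))
}

# Dataset from explicit call vectors (one row per sample).
ds_from_calls <- function(calls, bp = NULL, chrom = NULL, pop = NULL) {
  calls <- rbind(calls)
  n_snps <- ncol(calls)
  if (is.null(bp)) bp <- seq(1e5, by = 1e5, length.out = n_snps)
  if (is.null(chrom)) chrom <- rep("1", n_snps)
  n <- nrow(calls)
  geno_ds(calls,
          data.frame(chrom = chrom, snp_id = paste0("s", seq_len(n_snps)),
                     cm = 0, bp = bp, a1 = "A", a2 = "B"),
          data.frame(sample_id = paste0("ind", seq_len(n)),
                     population = pop %||% rep("P1", n),
                     sex = NA_integer_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Outbred dataset at fixed SNP spacing (linkage-equilibrium founders),
# the substrate for planted-tract recovery checks.
outbred_sim <- function(seed, n_samples = 20, n_chrom = 2,
                        chrom_length_bp = 6e7, spacing = 5e4, ...) {
  simulate_population(sim_config(
    pops = list(A = list(N = n_samples)), n_generations = 0,
    n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
    snp_spacing_bp = spacing, seed = seed, ...))
}
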