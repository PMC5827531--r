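#' Simulation configuration
#'
#' Parameterizes the diploid Wright-Fisher forward simulator used to
#' validate every pipeline stage against known truth. Standing variation
#' is initialized from a uniform founder allele-frequency spectrum (no new
#' mutation during the simulated epoch); populations either split from a
#' common simulated ancestral population or start from independent draws
#' of the same founder frequencies; each subsequent generation is formed
#' by multinomial resampling (random mating, selfing allowed) with
#' recombination, crossovers Poisson with mean equal to the chromosome's
#' genetic length. A selective sweep assigns genotype fitnesses
#' 1, 1+s, 1+2s at the swept site. Final SNP ascertainment keeps sites
#' with pooled MAF at or above `maf_ascertainment`, mimicking array
#' ascertainment.
#'
#' @param pops named list of populations, each a list with `N` (diploid
#'   size; a scalar or a per-generation vector of length `n_generations`
#'   for piecewise-constant histories).
#' @param n_generations generations simulated after the split.
#' @param n_chrom,chrom_length_bp genome layout.
#' @param n_snps_per_chrom SNP count per chromosome (uniform random
#'   positions), ignored when `snp_spacing_bp` is given.
#' @param snp_spacing_bp optional fixed SNP spacing in bp.
#' @param recomb_cm_per_mb recombination rate (1 cM/Mb default).
#' @param init_freq_range founder allele-frequency spectrum bounds.
#' @param ancestral_N,ancestral_generations optional shared ancestral
#'   phase before the split (0 generations = independent founder draws).
#' @param sweep `NULL` or a list with `population`, `chrom`, `bp`,
#'   `s` (selection coefficient), `mode` (`"hard"`, the default, plants
#'   the allele on a single haplotype of the sweep population and
#'   re-introduces it whenever it is lost before establishing, the
#'   standard way of conditioning on a completed hard sweep;
#'   `"standing"` re-seeds shared standing variation at `start_freq`,
#'   giving a soft sweep), `start_freq` (standing mode only, default
#'   0.1), `start_gen` (default 1) and `fix_threshold` (default 0.95):
#'   if the swept allele ends below the threshold the simulation is
#'   re-run with a different seed, up to `sweep_retry_cap` times.
#' @param planted_trios number of parent-parent-child trios appended
#'   after the simulation.
#' @param planted_autozygosity `NULL` or a list of lists with `sample`
#'   (index or id), `tracts` (data.frame `chrom`, `start_bp`, `end_bp`).
#' @param missing_rate,genotype_error_rate applied to the unphased view
#'   only (symmetric single-allele miscall).
#' @param maf_ascertainment pooled-MAF floor for retained SNPs.
#' @param samples_per_pop diploid samples emitted per population
#'   (default: all).
#' @param sweep_retry_cap maximum re-runs when the sweep is lost to
#'   drift.
#' @param seed integer seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(pops = list(pop1 = list(N = 100),
                                   pop2 = list(N = 100)),
                       n_generations = 100, n_chrom = 2,
                       chrom_length_bp = 1e8, n_snps_per_chrom = 1000,
                       snp_spacing_bp = NULL, recomb_cm_per_mb = 1,
                       init_freq_range = c(0.05, 0.95),
                       ancestral_N = NULL, ancestral_generations = 0,
                       sweep = NULL, planted_trios = 0,
                       planted_autozygosity = NULL, missing_rate = 0,
                       genotype_error_rate = 0, maf_ascertainment = 0.02,
                       samples_per_pop = NULL, sweep_retry_cap = 10,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  for (v in c(missing_rate, genotype_error_rate, maf_ascertainment))
    if (v < 0 || v > 1) stop("rates must lie in [0,1]")
  if (!is.null(sweep)) {
    sweep$mode <- sweep$mode %||% "hard"
    sweep$start_freq <- sweep$start_freq %||% 0.1
    sweep$start_gen <- sweep$start_gen %||% 1L
    sweep$fix_threshold <- sweep$fix_threshold %||% 0.95
    stopifnot(sweep$population %in% names(pops), sweep$s >= 0,
              sweep$mode %in% c("hard", "standing"))
  }
  structure(list(pops = pops, n_generations = as.integer(n_generations),
                 n_chrom = as.integer(n_chrom),
                 chrom_length_bp = chrom_length_bp,
                 n_snps_per_chrom = as.integer(n_snps_per_chrom),
                 snp_spacing_bp = snp_spacing_bp,
                 recomb_cm_per_mb = recomb_cm_per_mb,
                 init_freq_range = init_freq_range,
                 ancestral_N = ancestral_N,
                 ancestral_generations = as.integer(ancestral_generations),
                 sweep = sweep, planted_trios = as.integer(planted_trios),
                 planted_autozygosity = planted_autozygosity,
                 missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 maf_ascertainment = maf_ascertainment,
                 samples_per_pop = samples_per_pop,
                 sweep_retry_cap = as.integer(sweep_retry_cap),
                 seed = as.integer(seed)),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Genome geometry shared by the simulator and the planting helpers.
.sim_geometry <- function(cfg) {
  per_chrom <- lapply(seq_len(cfg$n_chrom), function(ch) {
    if (!is.null(cfg$snp_spacing_bp))
      bp <- seq(cfg$snp_spacing_bp, cfg$chrom_length_bp,
                by = cfg$snp_spacing_bp)
    else
      bp <- sort(sample.int(cfg$chrom_length_bp, cfg$n_snps_per_chrom))
    as.integer(bp)
  })
  n_per <- lengths(per_chrom)
  list(bp = per_chrom, n_per = n_per,
       cols = split(seq_len(sum(n_per)), rep(seq_len(cfg$n_chrom), n_per)),
       morgans = cfg$chrom_length_bp * cfg$recomb_cm_per_mb / 1e8)
}

# One recombinant gamete from a parent's two haplotype rows.
.gamete <- function(H, row1, row2, geom, cfg) {
  out <- integer(ncol(H))
  for (ch in seq_along(geom$bp)) {
    idx <- geom$cols[[ch]]
    nx <- stats::rpois(1L, geom$morgans)
    first <- stats::runif(1) < 0.5
    if (nx == 0L) {
      out[idx] <- H[if (first) row1 else row2, idx]
    } else {
      xp <- sort(stats::runif(nx)) * cfg$chrom_length_bp
      use2 <- (findInterval(geom$bp[[ch]], xp) + !first) %% 2L == 1L
      h <- H[row1, idx]
      h[use2] <- H[row2, idx][use2]
      out[idx] <- h
    }
  }
  out
}

# Advance one population one generation: H is the (2N_prev x L) haplotype
# matrix; returns a (2N_new x L) matrix. fitness: per-individual weights.
# Gametes without crossovers (the majority at ~1 Morgan per chromosome)
# are copied in one vectorized subset per chromosome.
.wf_generation <- function(H, n_new, geom, cfg, fitness = NULL) {
  n_prev <- nrow(H) / 2L
  n_gam <- 2L * n_new
  parents <- sample.int(n_prev, n_gam, replace = TRUE, prob = fitness)
  n_chrom <- length(geom$bp)
  nx <- matrix(stats::rpois(n_gam * n_chrom, geom$morgans), n_gam)
  first <- matrix(stats::runif(n_gam * n_chrom) < 0.5, n_gam)
  out <- matrix(0L, n_gam, ncol(H))
  for (ch in seq_len(n_chrom)) {
    idx <- geom$cols[[ch]]
    bpc <- as.double(geom$bp[[ch]])
    hap_rows <- 2L * parents - as.integer(first[, ch])
    plain <- nx[, ch] == 0L
    out[plain, idx] <- H[hap_rows[plain], idx, drop = FALSE]
    for (k in which(!plain)) {
      nxk <- nx[k, ch]
      if (nxk == 1L) {
        xp <- stats::runif(1L) * cfg$chrom_length_bp
        use2 <- if (first[k, ch]) bpc > xp else bpc <= xp
      } else {
        xp <- sort.int(stats::runif(nxk), method = "quick") *
          cfg$chrom_length_bp
        use2 <- (findInterval(bpc, xp) + !first[k, ch]) %% 2L == 1L
      }
      h <- H[2L * parents[k] - 1L, idx]
      h2 <- H[2L * parents[k], idx]
      h[use2] <- h2[use2]
      out[k, idx] <- h
    }
  }
  out
}

.sweep_fitness <- function(H, sweep_col, s) {
  dos <- H[seq(1, nrow(H), 2), sweep_col] + H[seq(2, nrow(H), 2), sweep_col]
  1 + s * dos
}

#' Simulate genotype data under the Wright-Fisher model
#'
#' Runs the forward simulation described in [sim_config()] and returns
#' both the phased truth and an unphased genotype-dataset view, plus
#' truth tables for every planted feature. Identical seeds give
#' bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return A `sim_output` list: `ds` (a [geno_ds()]; calls are the
#'   haplotype sums with genotype error and missingness applied),
#'   `haplotypes` (0/1 matrix, two consecutive rows per sample),
#'   `truth` (list: `sweep` with the realized swept SNP and final
#'   frequencies, `trios`, `ibd_tracts`, `n_trajectory`, `seed_used`),
#'   `config`.
#' @export
simulate_population <- function(cfg) {
  seed <- cfg$seed
  for (attempt in seq_len(cfg$sweep_retry_cap + 1L)) {
    out <- .simulate_once(cfg, seed)
    if (is.null(cfg$sweep)) return(out)
    if (out$truth$sweep$final_freq >= cfg$sweep$fix_threshold) return(out)
    seed <- seed + 99991L   # large prime step: retries of nearby base
  }                         # seeds never collide
  warning("sweep lost by drift in all ", cfg$sweep_retry_cap + 1L,
          " attempts; returning the last run (final frequency ",
          signif(out$truth$sweep$final_freq, 3), ")")
  out
}

.simulate_once <- function(cfg, seed) {
  set.seed(seed)
  geom <- .sim_geometry(cfg)
  L <- sum(geom$n_per)
  p0 <- stats::runif(L, cfg$init_freq_range[1], cfg$init_freq_range[2])
  pop_names <- names(cfg$pops)
  n_gen <- cfg$n_generations
  n_rows <- max(1L, n_gen)   # n_generations = 0 emits the founders
  size_mat <- vapply(cfg$pops, function(p) {
    if (length(p$N) == 1L) rep(as.integer(p$N), n_rows)
    else if (length(p$N) == n_gen) as.integer(p$N)
    else stop("population N must be scalar or length n_generations")
  }, integer(n_rows))
  if (n_rows == 1L) size_mat <- matrix(size_mat, nrow = 1L,
                                       dimnames = list(NULL, pop_names))

  draw_founders <- function(n_dip)
    matrix(stats::rbinom(2L * n_dip * L, 1L,
                         rep(p0, each = 2L * n_dip)), nrow = 2L * n_dip)

  if (cfg$ancestral_generations > 0L) {
    n_anc <- cfg$ancestral_N %||% max(size_mat[1, ])
    A <- draw_founders(n_anc)
    for (g in seq_len(cfg$ancestral_generations))
      A <- .wf_generation(A, n_anc, geom, cfg)
    H <- lapply(pop_names, function(p) .wf_generation(A, size_mat[1, p],
                                                      geom, cfg))
  } else {
    H <- lapply(pop_names, function(p) draw_founders(size_mat[1, p]))
  }
  names(H) <- pop_names

  sweep <- cfg$sweep
  sweep_col <- NA_integer_
  if (!is.null(sweep)) {
    cand <- geom$cols[[sweep$chrom]]
    sweep_col <- cand[which.min(abs(geom$bp[[sweep$chrom]] - sweep$bp))]
  }

  for (g in seq_len(n_gen)) {
    if (!is.null(sweep) && g == sweep$start_gen) {
      if (sweep$mode == "hard") {
        # a new mutation: absent everywhere, one carrier haplotype in
        # the sweep population
        for (p in pop_names) H[[p]][, sweep_col] <- 0L
        H[[sweep$population]][sample.int(
          nrow(H[[sweep$population]]), 1L), sweep_col] <- 1L
      } else {
        # soft sweep from shared standing variation at start_freq in
        # every population; only the sweep population selects on it
        for (p in pop_names) {
          hp <- H[[p]]
          n_hap <- nrow(hp)
          carriers <- sample.int(n_hap, max(1L, round(sweep$start_freq *
                                                        n_hap)))
          hp[, sweep_col] <- 0L
          hp[carriers, sweep_col] <- 1L
          H[[p]] <- hp
        }
      }
    }
    if (!is.null(sweep) && sweep$mode == "hard" && g > sweep$start_gen) {
      # condition on eventual fixation: re-introduce the mutation if it
      # drifts out before establishing
      hp <- H[[sweep$population]]
      cnt <- sum(hp[, sweep_col])
      if (cnt == 0L)
        H[[sweep$population]][sample.int(nrow(hp), 1L), sweep_col] <- 1L
    }
    for (p in pop_names) {
      fit <- NULL
      if (!is.null(sweep) && p == sweep$population && g >= sweep$start_gen)
        fit <- .sweep_fitness(H[[p]], sweep_col, sweep$s)
      H[[p]] <- .wf_generation(H[[p]], size_mat[g, p], geom, cfg, fit)
    }
  }

  # emit samples
  n_out <- vapply(pop_names, function(p)
    min(cfg$samples_per_pop %||% Inf, size_mat[n_rows, p]), 0)
  haps <- do.call(rbind, lapply(seq_along(pop_names), function(i) {
    pick <- seq_len(n_out[i])   # first n_out individuals (exchangeable)
    H[[i]][c(rbind(2L * pick - 1L, 2L * pick)), , drop = FALSE]
  }))
  sample_id <- unlist(lapply(seq_along(pop_names), function(i)
    sprintf("%s_%03d", pop_names[i], seq_len(n_out[i]))))
  population <- rep(pop_names, n_out)

  # SNP ascertainment on the pooled final sample
  p_pool <- colMeans(haps)
  keep <- pmin(p_pool, 1 - p_pool) >= cfg$maf_ascertainment
  if (!is.na(sweep_col)) keep[sweep_col] <- TRUE   # keep the swept site
  chrom_of <- rep(seq_len(cfg$n_chrom), geom$n_per)
  snps <- data.frame(chrom = as.character(chrom_of),
                     snp_id = sprintf("snp%d_%d", chrom_of,
                                      unlist(geom$bp)),
                     cm = unlist(geom$bp) * cfg$recomb_cm_per_mb / 1e6,
                     bp = unlist(geom$bp),
                     a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  haps <- haps[, keep, drop = FALSE]
  snps <- snps[keep, , drop = FALSE]

  hap_pop <- rep(population, each = 2L)
  truth <- list(
    sweep = if (!is.null(sweep)) list(
      snp_id = snps$snp_id[match(sweep_col, which(keep))],
      chrom = as.character(sweep$chrom),
      bp = unlist(geom$bp)[sweep_col],
      s = sweep$s,
      final_freq = mean(haps[hap_pop == sweep$population,
                             match(sweep_col, which(keep))]))
    else list(final_freq = NA_real_),
    trios = data.frame(parent1 = character(), parent2 = character(),
                       child = character()),
    ibd_tracts = data.frame(sample_id = character(), chrom = character(),
                            start_bp = integer(), end_bp = integer()),
    n_trajectory = size_mat, seed_used = seed)

  out <- structure(list(
    haplotypes = haps,
    ds = .haps_to_ds(haps, snps, sample_id, population, cfg),
    truth = truth, config = cfg, geom_snps = snps),
    class = "sim_output")

  if (cfg$planted_trios > 0L) {
    ids <- sample_id
    for (k in seq_len(cfg$planted_trios)) {
      pr <- sample(ids, 2L)
      out <- plant_trio(out, pr)
      ids <- setdiff(ids, pr)   # distinct parents across trios
    }
  }
  if (!is.null(cfg$planted_autozygosity))
    for (pl in cfg$planted_autozygosity)
      out <- plant_autozygosity(out, pl$sample, pl$tracts)
  out
}

# Unphased view: dosage = hap1 + hap2, then genotype error (symmetric
# single-allele miscall) and missingness.
.haps_to_ds <- function(haps, snps, sample_id, population, cfg) {
  n <- length(sample_id)
  calls <- haps[seq(1, 2 * n, 2), , drop = FALSE] +
    haps[seq(2, 2 * n, 2), , drop = FALSE]
  storage.mode(calls) <- "integer"
  if (cfg$genotype_error_rate > 0) {
    err <- which(stats::runif(length(calls)) < cfg$genotype_error_rate)
    for (i in err) {
      g <- calls[i]
      calls[i] <- if (g == 0L) 1L else if (g == 2L) 1L
      else if (stats::runif(1) < 0.5) 0L else 2L
    }
  }
  if (cfg$missing_rate > 0)
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
  geno_ds(calls, snps,
          data.frame(sample_id = sample_id, population = population,
                     sex = NA_integer_, stringsAsFactors = FALSE))
}

#' Append a planted parent-offspring trio
#'
#' Creates a child whose haplotypes are recombinant gametes of the two
#' named parents and appends it (same population as parent 1). The truth
#' table of pedigree links is updated.
#'
#' @param out a `sim_output`.
#' @param parent_ids length-2 character vector of existing sample ids.
#' @param child_id id for the child (default derived from the parents).
#' @return The updated `sim_output`.
#' @export
plant_trio <- function(out, parent_ids, child_id = NULL) {
  cfg <- out$config
  geom <- .sim_geometry_from_snps(out$geom_snps, cfg)
  ids <- out$ds$samples$sample_id
  i1 <- match(parent_ids[1], ids)
  i2 <- match(parent_ids[2], ids)
  if (anyNA(c(i1, i2))) stop("parent id(s) not found")
  child_id <- child_id %||% paste0("child_", parent_ids[1], "_x_",
                                   parent_ids[2])
  g1 <- .gamete(out$haplotypes, 2L * i1 - 1L, 2L * i1, geom, cfg)
  g2 <- .gamete(out$haplotypes, 2L * i2 - 1L, 2L * i2, geom, cfg)
  out$haplotypes <- rbind(out$haplotypes, g1, g2)
  rownames(out$haplotypes) <- NULL
  samples <- rbind(out$ds$samples,
                   data.frame(sample_id = child_id,
                              population = out$ds$samples$population[i1],
                              sex = NA_integer_))
  out$ds <- .haps_to_ds(out$haplotypes, out$ds$snps, samples$sample_id,
                        samples$population, cfg)
  out$truth$trios <- rbind(out$truth$trios,
                           data.frame(parent1 = parent_ids[1],
                                      parent2 = parent_ids[2],
                                      child = child_id))
  out
}

#' Plant autozygous tracts into a sample
#'
#' Within each tract the sample's second haplotype is overwritten with a
#' copy of the first, producing exact identity-by-descent. The truth
#' table of IBD tracts is updated.
#'
#' @param out a `sim_output`.
#' @param sample sample id or index.
#' @param tracts data.frame with columns `chrom`, `start_bp`, `end_bp`
#'   (1-based inclusive, non-overlapping, within chromosomes).
#' @return The updated `sim_output`.
#' @export
plant_autozygosity <- function(out, sample, tracts) {
  ids <- out$ds$samples$sample_id
  i <- if (is.character(sample)) match(sample, ids) else as.integer(sample)
  if (is.na(i) || i < 1L || i > length(ids)) stop("sample not found")
  if (nrow(tracts) == 0L) return(out)
  for (k in seq_len(nrow(tracts))) {
    jj <- which(out$ds$snps$chrom == as.character(tracts$chrom[k]) &
                  out$ds$snps$bp >= tracts$start_bp[k] &
                  out$ds$snps$bp <= tracts$end_bp[k])
    out$haplotypes[2L * i, jj] <- out$haplotypes[2L * i - 1L, jj]
  }
  out$ds <- .haps_to_ds(out$haplotypes, out$ds$snps,
                        out$ds$samples$sample_id,
                        out$ds$samples$population, out$config)
  out$truth$ibd_tracts <- rbind(
    out$truth$ibd_tracts,
    data.frame(sample_id = ids[i], chrom = as.character(tracts$chrom),
               start_bp = tracts$start_bp, end_bp = tracts$end_bp))
  out
}

# Geometry reconstructed from an ascertained SNP table (for planting after
# ascertainment has dropped columns).
.sim_geometry_from_snps <- function(snps, cfg) {
  chroms <- as.character(seq_len(cfg$n_chrom))
  bp <- lapply(chroms, function(ch) snps$bp[snps$chrom == ch])
  n_per <- lengths(bp)
  list(bp = bp, n_per = n_per,
       cols = split(seq_len(sum(n_per)),
                    factor(snps$chrom, levels = chroms)),
       morgans = cfg$chrom_length_bp * cfg$recomb_cm_per_mb / 1e8)
}

#' @export
print.sim_output <- function(x, ...) {
  cat("Wright-Fisher simulation output (seed ", x$truth$seed_used, ")\n",
      sep = "")
  print(x$ds)
  if (!is.null(x$config$sweep))
    cat(sprintf("  sweep: s=%.3g at %s:%d, final frequency %.3f\n",
                x$truth$sweep$s, x$truth$sweep$chrom, x$truth$sweep$bp,
                x$truth$sweep$final_freq))
  if (nrow(x$truth$trios))
    cat("  planted trios:", nrow(x$truth$trios), "\n")
  if (nrow(x$truth$ibd_tracts))
    cat("  planted IBD tracts:", nrow(x$truth$ibd_tracts), "\n")
  invisible(x)
}
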