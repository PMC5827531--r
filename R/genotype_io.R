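# Default autosome set for cattle (Bos taurus has 29 autosome pairs).
.default_autosomes <- as.character(1:29)

#' Construct a genotype dataset
#'
#' The common in-memory currency of all pipeline stages: a sample table, a
#' SNP map and a calls matrix. Genotype calls count copies of `a2` at each
#' locus (0, 1, 2) with `NA` for missing; missing is a distinct sentinel and
#' never conflated with the homozygous-0 state. Downstream statistics
#' (heterozygosity, minor allele frequency, IBS) are invariant to which
#' allele is labelled `a2`.
#'
#' @param calls integer matrix, samples in rows and SNPs in columns, values
#'   in `c(0L, 1L, 2L, NA)`.
#' @param snps data.frame with columns `chrom` (character), `snp_id`, `cm`,
#'   `bp` (1-based position), `a1`, `a2`.
#' @param samples data.frame with columns `sample_id`, `population` and
#'   optionally `sex`.
#' @return An object of class `geno_ds`.
#' @export
geno_ds <- function(calls, snps, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 1L, 2L) | is.na(calls)))
    stop("genotype calls must be 0, 1, 2 or NA")
  if (nrow(calls) != nrow(samples))
    stop("calls has ", nrow(calls), " rows but samples has ", nrow(samples))
  if (ncol(calls) != nrow(snps))
    stop("calls has ", ncol(calls), " columns but snps has ", nrow(snps))
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp_id in map")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (any(snps$bp < 1)) stop("bp positions must be >= 1")
  snps$chrom <- as.character(snps$chrom)
  if (is.null(snps$cm)) snps$cm <- 0
  rownames(calls) <- samples$sample_id
  colnames(calls) <- snps$snp_id
  rownames(snps) <- NULL
  rownames(samples) <- NULL
  structure(list(calls = calls, snps = snps, samples = samples),
            class = "geno_ds")
}

#' @export
print.geno_ds <- function(x, ...) {
  cat("A genotype dataset (geno_ds)\n")
  cat("  samples:", nrow(x$samples), "in",
      length(unique(x$samples$population)), "population(s)\n")
  cat("  SNPs:   ", nrow(x$snps), "on",
      length(unique(x$snps$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.geno_ds <- function(object, ...) {
  pops <- table(object$samples$population)
  chroms <- table(object$snps$chrom)
  list(n_samples = nrow(object$samples), n_snps = nrow(object$snps),
       populations = pops, snps_per_chrom = chroms,
       missing_rate = mean(is.na(object$calls)))
}

# Order SNP table and calls by (chrom, bp); chromosome order is numeric
# where labels are numeric, lexicographic otherwise.
.sort_snps <- function(ds) {
  chrom_key <- suppressWarnings(as.numeric(ds$snps$chrom))
  if (anyNA(chrom_key)) chrom_key <- ds$snps$chrom
  o <- order(chrom_key, ds$snps$bp)
  ds$snps <- ds$snps[o, , drop = FALSE]
  rownames(ds$snps) <- NULL
  ds$calls <- ds$calls[, o, drop = FALSE]
  ds
}

.filter_autosomes <- function(ds, autosomes) {
  keep <- ds$snps$chrom %in% autosomes
  ds$snps <- ds$snps[keep, , drop = FALSE]
  rownames(ds$snps) <- NULL
  ds$calls <- ds$calls[, keep, drop = FALSE]
  ds
}

#' Read PLINK text (ped/map) genotypes
#'
#' Parses a ped/map file pair into a [geno_ds()]. Genotypes are recoded to
#' 0/1/2 copies of the `a2` allele with `0 0` treated as missing.
#' Non-autosomal SNPs are dropped and SNPs are sorted by (chrom, bp). At
#' each locus the less frequent observed allele becomes `a1` and the more
#' frequent `a2` (alphabetical tie-break); monomorphic loci get `a1 = "0"`.
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @param autosomes character vector of chromosome labels retained
#'   (default `"1"`..`"29"`, the cattle autosomes).
#' @return A [geno_ds()].
#' @export
read_plink_text <- function(ped_path, map_path,
                            autosomes = .default_autosomes) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  bad <- which(!lengths(map_tok) %in% c(3L, 4L))
  if (length(bad))
    stop("malformed map line ", bad[1], ": expected 3 or 4 fields")
  has_cm <- lengths(map_tok) == 4L
  chrom <- vapply(map_tok, `[`, "", 1L)
  snp_id <- vapply(map_tok, `[`, "", 2L)
  cm <- ifelse(has_cm, as.numeric(vapply(map_tok, `[`, "", 3L)), 0)
  bp <- as.integer(vapply(map_tok, function(t) t[length(t)], ""))
  if (anyNA(bp)) stop("malformed map line ",
                      which(is.na(bp))[1], ": bad bp position")
  n_snp <- length(snp_id)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n_samp <- length(ped_lines)
  a_mat <- matrix("0", nrow = 2L * n_samp, ncol = n_snp)
  sample_id <- character(n_samp)
  population <- character(n_samp)
  sex <- integer(n_samp)
  for (i in seq_len(n_samp)) {
    tok <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6L + 2L * n_snp)
      stop("malformed ped line ", i, ": expected ", 6L + 2L * n_snp,
           " fields, found ", length(tok))
    population[i] <- tok[1]
    sample_id[i] <- tok[2]
    sex[i] <- suppressWarnings(as.integer(tok[5]))
    a_mat[2L * i - 1L, ] <- tok[seq(7L, by = 2L, length.out = n_snp)]
    a_mat[2L * i, ] <- tok[seq(8L, by = 2L, length.out = n_snp)]
  }

  calls <- matrix(NA_integer_, nrow = n_samp, ncol = n_snp)
  a1 <- character(n_snp)
  a2 <- character(n_snp)
  for (j in seq_len(n_snp)) {
    al <- a_mat[, j]
    obs <- al[al != "0"]
    lev <- sort(unique(obs))
    if (length(lev) > 2L)
      stop("locus ", snp_id[j], " has more than 2 alleles: ",
           paste(lev, collapse = "/"))
    if (length(lev) == 0L) { a1[j] <- "0"; a2[j] <- "0"; next }
    if (length(lev) == 1L) {
      a1[j] <- "0"; a2[j] <- lev
    } else {
      cnt <- table(factor(obs, levels = lev))
      # minor allele first; alphabetical on ties (sort() already applied)
      if (cnt[[1]] <= cnt[[2]]) { a1[j] <- lev[1]; a2[j] <- lev[2] }
      else { a1[j] <- lev[2]; a2[j] <- lev[1] }
    }
    h1 <- a_mat[seq(1L, by = 2L, length.out = n_samp), j]
    h2 <- a_mat[seq(2L, by = 2L, length.out = n_samp), j]
    g <- (h1 == a2[j]) + (h2 == a2[j])
    g[h1 == "0" | h2 == "0"] <- NA_integer_
    calls[, j] <- as.integer(g)
  }

  ds <- geno_ds(calls,
                data.frame(chrom = chrom, snp_id = snp_id, cm = cm, bp = bp,
                           a1 = a1, a2 = a2, stringsAsFactors = FALSE),
                data.frame(sample_id = sample_id, population = population,
                           sex = sex, stringsAsFactors = FALSE))
  .sort_snps(.filter_autosomes(ds, autosomes))
}

# PLINK 1 binary magic bytes and the 2-bit genotype code table.
# SNP-major layout: one byte packs four samples, low bits first.
# 00 = hom a1 (0 copies of a2), 01 = missing, 10 = het, 11 = hom a2.
.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))
.bed_code_to_call <- c(0L, NA_integer_, 1L, 2L)   # index by code + 1
.call_to_bed_code <- function(g) {
  code <- integer(length(g))
  code[is.na(g)] <- 1L
  code[!is.na(g) & g == 1L] <- 2L
  code[!is.na(g) & g == 2L] <- 3L
  code
}

#' Read PLINK binary (bed/bim/fam) genotypes
#'
#' Decodes a SNP-major PLINK v1.00 .bed file (magic bytes 0x6c 0x1b 0x01)
#' together with its .bim and .fam companions. Produces the same
#' [geno_ds()] as [read_plink_text()] would for equivalent content.
#'
#' @inheritParams read_plink_text
#' @param bed_path,bim_path,fam_path paths to the three PLINK binary files.
#' @return A [geno_ds()].
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path,
                              autosomes = .default_autosomes) {
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "snp_id", "cm", "bp", "a1", "a2")
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  n_snp <- nrow(bim)
  n_samp <- nrow(fam)
  raw <- readBin(bed_path, "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3L || !identical(raw[1:3], .bed_magic))
    stop("bad magic bytes: not a PLINK v1.00 SNP-major bed file")
  bytes_per_snp <- ceiling(n_samp / 4)
  expected <- 3L + n_snp * bytes_per_snp
  if (length(raw) != expected)
    stop("bed file truncated or oversized: expected ", expected,
         " bytes, found ", length(raw))
  body <- raw[-(1:3)]
  # unpack all 2-bit codes at once
  m <- matrix(as.integer(body), nrow = bytes_per_snp)
  codes <- rbind(m %% 4L, (m %/% 4L) %% 4L, (m %/% 16L) %% 4L, m %/% 64L)
  # rows are interleaved (all bit-pair 0 first); reorder to sample order
  codes <- codes[order(rep(seq_len(bytes_per_snp), 4L),
                       rep(1:4, each = bytes_per_snp)), , drop = FALSE]
  codes <- codes[seq_len(n_samp), , drop = FALSE]
  calls <- matrix(.bed_code_to_call[codes + 1L], nrow = n_samp)

  ds <- geno_ds(calls, bim,
                data.frame(sample_id = fam[[2]], population = fam[[1]],
                           sex = suppressWarnings(as.integer(fam[[5]])),
                           stringsAsFactors = FALSE))
  .sort_snps(.filter_autosomes(ds, autosomes))
}

#' Read PLINK genotypes, auto-detecting the dialect
#'
#' @param prefix path prefix; `prefix.bed/.bim/.fam` is preferred if
#'   present, else `prefix.ped/.map`.
#' @inheritParams read_plink_text
#' @return A [geno_ds()].
#' @export
read_plink <- function(prefix, autosomes = .default_autosomes) {
  if (file.exists(paste0(prefix, ".bed")))
    read_plink_binary(paste0(prefix, ".bed"), paste0(prefix, ".bim"),
                      paste0(prefix, ".fam"), autosomes)
  else if (file.exists(paste0(prefix, ".ped")))
    read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"),
                    autosomes)
  else stop("no PLINK files found at prefix: ", prefix)
}

#' Write a genotype dataset as PLINK text (ped/map)
#'
#' @param ds a [geno_ds()].
#' @param prefix output path prefix; writes `prefix.ped` and `prefix.map`.
#' @return The prefix, invisibly.
#' @export
write_plink_text <- function(ds, prefix) {
  map <- with(ds$snps, paste(chrom, snp_id, cm, bp))
  writeLines(map, paste0(prefix, ".map"))
  n_snp <- nrow(ds$snps)
  a1 <- ds$snps$a1
  a2 <- ds$snps$a2
  a1[a1 == "0"] <- a2[a1 == "0"]   # monomorphic: emit the single allele
  lines <- vapply(seq_len(nrow(ds$samples)), function(i) {
    g <- ds$calls[i, ]
    h1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, a2, a1))
    h2 <- ifelse(is.na(g), "0", ifelse(g == 2L, a2, a1))
    geno <- character(2L * n_snp)
    geno[seq(1L, by = 2L, length.out = n_snp)] <- h1
    geno[seq(2L, by = 2L, length.out = n_snp)] <- h2
    s <- ds$samples[i, ]
    sex <- if (!is.null(s$sex) && !is.na(s$sex)) s$sex else 0
    paste(s$population, s$sample_id, 0, 0, sex, -9,
          paste(geno, collapse = " "))
  }, "")
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Write a genotype dataset as PLINK binary (bed/bim/fam)
#'
#' Emits a SNP-major v1.00 bed file plus bim/fam companions.
#'
#' @inheritParams write_plink_text
#' @return The prefix, invisibly.
#' @export
write_plink_binary <- function(ds, prefix) {
  bim <- with(ds$snps, paste(chrom, snp_id, cm, bp, a1, a2, sep = "\t"))
  writeLines(bim, paste0(prefix, ".bim"))
  fam <- vapply(seq_len(nrow(ds$samples)), function(i) {
    s <- ds$samples[i, ]
    sex <- if (!is.null(s$sex) && !is.na(s$sex)) s$sex else 0
    paste(s$population, s$sample_id, 0, 0, sex, -9)
  }, "")
  writeLines(fam, paste0(prefix, ".fam"))
  n_samp <- nrow(ds$samples)
  bytes_per_snp <- ceiling(n_samp / 4)
  pad <- 4L * bytes_per_snp - n_samp
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  out <- vapply(seq_len(ncol(ds$calls)), function(j) {
    code <- c(.call_to_bed_code(ds$calls[, j]), integer(pad))
    cm <- matrix(code, nrow = 4L)
    as.raw(cm[1, ] + 4L * cm[2, ] + 16L * cm[3, ] + 64L * cm[4, ])
  }, raw(bytes_per_snp))
  writeBin(as.raw(out), con)
  invisible(prefix)
}

#' Subset a genotype dataset by sample and/or SNP ids
#'
#' Order-preserving restriction: retained rows and columns keep the order of
#' the input dataset, not of the id sets.
#'
#' @param ds a [geno_ds()].
#' @param sample_ids character vector of sample ids to keep, or `NULL` for
#'   all.
#' @param snp_ids character vector of SNP ids to keep, or `NULL` for all.
#' @return A [geno_ds()].
#' @export
subset_geno <- function(ds, sample_ids = NULL, snp_ids = NULL) {
  keep_s <- rep(TRUE, nrow(ds$samples))
  keep_j <- rep(TRUE, nrow(ds$snps))
  if (!is.null(sample_ids)) {
    unknown <- setdiff(sample_ids, ds$samples$sample_id)
    if (length(unknown)) stop("unknown sample id(s): ",
                              paste(unknown, collapse = ", "))
    keep_s <- ds$samples$sample_id %in% sample_ids
  }
  if (!is.null(snp_ids)) {
    unknown <- setdiff(snp_ids, ds$snps$snp_id)
    if (length(unknown)) stop("unknown SNP id(s): ",
                              paste(unknown, collapse = ", "))
    keep_j <- ds$snps$snp_id %in% snp_ids
  }
  geno_ds(ds$calls[keep_s, keep_j, drop = FALSE],
          ds$snps[keep_j, , drop = FALSE],
          ds$samples[keep_s, , drop = FALSE])
}

# Population -> row indices helper used across modules.
.pop_rows <- function(ds, population) {
  rows <- which(ds$samples$population == population)
  if (!length(rows)) stop("population not present: ", population)
  rows
}
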