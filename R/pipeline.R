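#' Run the full analysis pipeline
#'
#' Executes the study stages in their canonical order on one dataset:
#' (1) kinship screen and parent-offspring exclusion, (2) SNP/sample QC,
#' (3) observed heterozygosity and IBS matrix, (4) ROH detection and
#' F_ROH (on a no-MAF-filter QC pass of the same input), (5) LD-based
#' N_e trajectory per population (MAF 0.05 pass), and (6) the composite
#' selection scan when a contrast is configured. Each stage's parameters
#' are hashed into a JSON manifest; re-running with the same
#' configuration and seed reproduces byte-identical tables.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{input}{PLINK prefix to read, or `NULL` to simulate.}
#'     \item{sim}{[sim_config()] arguments (used when `input` is NULL).}
#'     \item{qc}{[qc_config()] arguments.}
#'     \item{roh}{[roh_config()] arguments.}
#'     \item{ne}{[ne_config()] arguments plus `populations` (default:
#'       all).}
#'     \item{css}{[contrast_config()] arguments, or `NULL` to skip the
#'       scan.}
#'     \item{kinship}{list with `error_allowance` (default 0.005).}
#'     \item{out_dir}{output directory for tables and the manifest.}
#'     \item{seed}{global seed; stage seeds are derived from it.}
#'   }
#' @return The run manifest (list, also written as
#'   `manifest.json` under `out_dir`), with each stage's parameter hash
#'   and headline numbers. The stage results themselves are attached in
#'   the `results` attribute.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- .read_config_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% tempfile("herdgen_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "herdgen",
                   version = as.character(utils::packageVersion("herdgen")),
                   seed = seed, stages = list())
  results <- list()
  add_stage <- function(name, params, summary) {
    manifest$stages[[name]] <<- list(name = name,
                                     params_hash = .param_hash(params),
                                     summary = summary)
  }

  # -- input (recorded in the manifest, not counted as a stage) -------
  haplotypes <- NULL
  if (!is.null(config$input)) {
    ds <- read_plink(config$input)
    manifest$input <- list(source = config$input,
                           params_hash = .param_hash(config$input),
                           n_samples = nrow(ds$samples),
                           n_snps = nrow(ds$snps))
  } else {
    sim_args <- config$sim %||% list()
    sim_args$seed <- sim_args$seed %||% (seed + 101L)
    sim <- simulate_population(do.call(sim_config, sim_args))
    ds <- sim$ds
    haplotypes <- sim$haplotypes
    results$sim <- sim
    manifest$input <- list(source = "simulated",
                           params_hash = .param_hash(sim_args),
                           n_samples = nrow(ds$samples),
                           n_snps = nrow(ds$snps))
  }

  # -- kinship exclusion ---------------------------------------------
  allowance <- config$kinship$error_allowance %||% 0.005
  kin <- detect_parent_offspring(ds, allowance)
  ds_kin <- remove_pair_members(ds, kin$pairs, seed = seed + 1L)
  removed <- attr(ds_kin, "removed") %||% character(0)
  if (!is.null(haplotypes)) {
    keep <- ds$samples$sample_id %in% ds_kin$samples$sample_id
    haplotypes <- haplotypes[rep(keep, each = 2L), , drop = FALSE]
  }
  results$kinship <- kin
  add_stage("kinship", list(error_allowance = allowance, seed = seed + 1L),
            list(pairs_detected = nrow(kin$pairs),
                 samples_removed = removed))

  # -- QC (three passes sharing the sample set) -----------------------
  qc_args <- config$qc %||% list()
  cfg_main <- do.call(qc_config, qc_args)
  qc <- apply_qc(ds_kin, cfg_main)
  results$qc <- qc
  if (!is.null(haplotypes)) {
    keep <- ds_kin$samples$sample_id %in% qc$dataset$samples$sample_id
    haplotypes <- haplotypes[rep(keep, each = 2L), , drop = FALSE]
  }
  add_stage("qc", unclass(cfg_main),
            list(snps_retained = qc$report$snps_retained,
                 samples_removed = qc$report$samples_removed,
                 removed_by_rule = as.list(qc$report$snps_removed_by_rule)))

  # ROH pass: no MAF filter; Ne pass: MAF 0.05
  cfg_qc_roh <- cfg_main
  cfg_qc_roh["min_maf"] <- list(NULL)
  ds_roh <- apply_qc(ds_kin, cfg_qc_roh)$dataset
  cfg_qc_ne <- cfg_main
  cfg_qc_ne$min_maf <- 0.05
  ds_ne <- apply_qc(ds_kin, cfg_qc_ne)$dataset

  # -- heterozygosity + IBS ------------------------------------------
  ibs <- ibs_matrix(qc$dataset)
  results$ibs <- ibs
  utils::write.table(ibs$ibs, file.path(out_dir, "ibs_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  add_stage("ho_ibs", list(),
            list(ho = as.list(qc$report$ho_by_population)))

  # -- ROH / F_ROH ----------------------------------------------------
  cfg_roh_scan <- do.call(roh_config, config$roh %||% list())
  segments <- suppressWarnings(detect_roh(ds_roh, cfg_roh_scan))
  froh <- compute_froh(segments, ds_roh)
  results$roh <- segments
  results$froh <- froh
  write_roh_bed(segments, file.path(out_dir, "roh_segments.bed"))
  utils::write.table(froh, file.path(out_dir, "froh.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  froh_cmp <- if (length(unique(froh$population)) >= 2L &&
                  all(table(froh$population) >= 2L))
    suppressWarnings(compare_froh(froh)) else NULL
  results$froh_comparison <- froh_cmp
  add_stage("roh", unclass(cfg_roh_scan),
            list(n_segments = nrow(segments),
                 mean_froh = as.list(tapply(froh$f_roh, froh$population,
                                            mean))))

  # -- Ne -------------------------------------------------------------
  ne_args <- config$ne %||% list()
  ne_pops <- ne_args$populations %||% unique(ds_ne$samples$population)
  ne_args$populations <- NULL
  cfg_ne <- do.call(ne_config, ne_args)
  ne_list <- lapply(ne_pops, function(p)
    tryCatch(suppressWarnings(ne_trajectory(ds_ne, p, cfg_ne)),
             error = function(e) NULL))
  names(ne_list) <- ne_pops
  results$ne <- ne_list
  for (p in ne_pops)
    if (!is.null(ne_list[[p]]))
      utils::write.table(ne_list[[p]],
                         file.path(out_dir, paste0("ne_", p, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  add_stage("ne", unclass(cfg_ne), list(
    recent_ne = lapply(ne_list, function(x)
      if (is.null(x) || !nrow(x)) NA else x$n_t[1])))

  # -- CSS ------------------------------------------------------------
  if (!is.null(config$css)) {
    css_args <- config$css
    css_args$seed <- css_args$seed %||% (seed + 5L)
    cfg_css <- do.call(contrast_config, css_args)
    hap_for_scan <- NULL
    if (!is.null(haplotypes)) {
      m <- match(qc$dataset$snps$snp_id, ds$snps$snp_id)
      hap_for_scan <- haplotypes[, m, drop = FALSE]
    }
    scan <- selection_scan(qc$dataset, cfg_css, hap_for_scan)
    results$css <- scan
    utils::write.table(scan$table, file.path(out_dir, "css_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_stage("css", unclass(cfg_css),
              list(n_snps = sum(!is.na(scan$table$css)),
                   n_peaks = nrow(scan$peaks)))
  }

  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  attr(manifest, "results") <- results
  invisible(manifest)
}

# YAML 1.1 parses a bare key `N` as boolean FALSE; restore it so
# population sizes can be written naturally in config files.
.read_config_yaml <- function(path) {
  fix <- function(x) {
    if (!is.list(x)) return(x)
    nm <- names(x)
    if (!is.null(nm)) names(x) <- ifelse(nm == "FALSE", "N", nm)
    lapply(x, fix)
  }
  fix(yaml::read_yaml(path))
}

# Stable hash of a parameter list: md5 of its canonical JSON encoding.
.param_hash <- function(params) {
  tf <- tempfile()
  on.exit(unlink(tf))
  jsonlite::write_json(params, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}
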