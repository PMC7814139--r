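# Pipeline orchestration: simulate/load -> QC -> ancestry PCA ->
# single-marker association -> SBA -> competitive, with one config, seeded
# reproducibility and a manifest of stage outputs. The numbered scripts
# under analysis/ are thin drivers over these functions.

#' Pipeline configuration
#'
#' Either `plink_prefix` + `gmt_path` + `gene_ranges_path` (real inputs)
#' or `sim` (a [sim_config()], demo mode) must be given. Unknown keys are
#' rejected by construction.
#'
#' @param out_dir output directory for stage artifacts.
#' @param plink_prefix,gmt_path,gene_ranges_path input file locations.
#' @param sim a [sim_config()] used instead of file inputs.
#' @param qc a [qc_thresholds()].
#' @param sba a [sba_params()].
#' @param competitive list(`max_perm`, `stop_exceedances`).
#' @param n_pcs_covariates PCs used as association covariates (default 5,
#'   the number of ancestry axes typically significant in structured
#'   European cohorts).
#' @param min_set_genes gene-set size floor (default 10).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, plink_prefix = NULL, gmt_path = NULL,
                            gene_ranges_path = NULL, sim = NULL,
                            qc = qc_thresholds(), sba = sba_params(),
                            competitive = list(max_perm = 2000,
                                               stop_exceedances = 10),
                            n_pcs_covariates = 5, min_set_genes = 10,
                            seed = 1) {
  if (is.null(sim) &&
      (is.null(plink_prefix) || is.null(gmt_path) || is.null(gene_ranges_path)))
    stop("give either sim or plink_prefix + gmt_path + gene_ranges_path")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

.write_manifest <- function(manifest, path) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(paste(names(unlist(manifest)), unlist(manifest), sep = "\t"),
               sub("\\.json$", ".tsv", path))
  }
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages run in order (QC, PCA, association, SBA, competitive); each
#' writes its TSV outputs under `config$out_dir` and the manifest records
#' them together with the seed and thresholds. Reruns with an identical
#' config are identical (stochastic stages are seeded).
#'
#' @param config a [pipeline_config()].
#' @return list: `manifest` (stage -> file paths), `dataset` (post-QC),
#'   `pca`, `scan`, `sba`, `competitive`, `qc_report`, and `truth` in demo
#'   mode.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(seed = config$seed)
  pth <- function(...) file.path(config$out_dir, paste0(...))

  if (!is.null(config$sim)) {
    sim <- simulate_cohort(config$sim)
    ds <- sim$dataset; genes <- sim$genes; sets <- sim$sets
    truth <- sim$truth
  } else {
    ds <- read_plink(config$plink_prefix)
    genes <- read_gene_ranges(config$gene_ranges_path)
    sets <- read_gmt(config$gmt_path)
    truth <- NULL
  }
  sets <- filter_gene_sets(sets, config$min_set_genes)
  man$input <- list(samples = n_samples(ds), markers = n_variants(ds),
                    sets = n_sets(sets))

  qc <- run_qc(ds, config$qc)
  ds <- orient_minor_allele(qc$dataset)
  man$qc <- as.list(write_qc_report(qc$report, pth("qc")))

  pca <- pca_patterson(ds, K = max(config$n_pcs_covariates,
                                   config$qc$pca_n_pcs))
  man$pca <- as.list(write_pca_result(pca, pth("pca")))
  # significant-axis count from the LD-regressed spectrum (calibrated TW)
  man$pca$n_significant <-
    pca_patterson(ds, K = 2, ld_regress = 5)$n_significant
  covar <- pca$scores[, seq_len(min(config$n_pcs_covariates,
                                    ncol(pca$scores))), drop = FALSE]

  scan <- gwas_scan(ds, covar)
  man$assoc <- write_assoc_results(scan, pth("assoc.tsv"))

  gene_map <- assign_snps_to_genes(ds$variants, genes,
                                   config$sba$window_kb)
  sba <- sba_test(ds, sets, gene_map = gene_map, covariates = covar,
                  params = config$sba)
  man$sba <- as.list(write_sba_results(sba, pth("sba")))
  man$sba$bonferroni <- bonferroni_threshold(n_sets(sets),
                                             config$sba$alpha)

  snp_p <- setNames(scan$P, scan$SNP)
  gs <- compute_gene_stats(ds, gene_map, snp_p, genes)
  comp <- adaptive_permutation_correction(
    gs, sets, max_perm = config$competitive$max_perm,
    stop_exceedances = config$competitive$stop_exceedances,
    seed = config$seed)
  man$competitive <- as.list(write_competitive_results(gs, comp,
                                                       pth("competitive")))
  man$competitive$fw_threshold <- attr(comp, "fw_threshold")

  .write_manifest(man, pth("manifest.json"))
  list(manifest = man, dataset = ds, qc_report = qc$report, pca = pca,
       scan = scan, sba = sba, competitive = comp, gene_stats = gs,
       truth = truth)
}

#' Write a demo fixture bundle
#'
#' Simulates a study-shaped cohort (45 gene sets after filtering, one
#' planted enriched set) and writes the PLINK trio, gene-range TSV, GMT,
#' truth table and config JSON under `out_dir`.
#'
#' @param out_dir output directory.
#' @param config a [sim_config()]; the default plants one enriched set.
#' @return invisibly, the file paths written.
#' @export
make_demo <- function(out_dir,
                      config = sim_config(
                        n_cases = 300, n_controls = 300, n_blocks = 20,
                        n_sets = 45, genes_per_block = 5,
                        causal_sets = list(list(set = "set01", n_causal = 5,
                                                or = 1.5)),
                        seed = 42)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config)
  paths <- c(
    write_plink(sim$dataset, file.path(out_dir, "cohort")),
    genes = write_gene_ranges(sim$genes, file.path(out_dir, "genes.tsv")),
    gmt = write_gmt(sim$sets, file.path(out_dir, "sets.gmt")),
    truth = file.path(out_dir, "truth.tsv"),
    config = file.path(out_dir, "sim_config.json"))
  write.table(sim$truth$causal, paths[["truth"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  .write_manifest(unclass(config)[setdiff(names(config), "pop_props")],
                  paths[["config"]])
  invisible(paths)
}
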