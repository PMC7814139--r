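#!/usr/bin/env Rscript
# Stage 1: build the demo cohort.
#
# A structured case-control cohort with LD blocks, two genotyping batches,
# 45 gene sets and one planted enriched set (5 causal SNPs, OR 1.5, all in
# one gene), plus planted QC pathologies: a near-duplicate sample, a
# low-call-rate sample, and ten batch-shifted markers. Everything
# downstream (QC -> PCA -> association -> SBA -> competitive) works from
# the files this stage writes.

library(pathgwas)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 42L
out <- file.path("results", "demo")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  n_cases = 400, n_controls = 400, n_blocks = 100, n_sets = 45,
  genes_per_block = 5,
  causal_sets = list(list(set = "set01", n_causal = 5, or = 1.5,
                          one_gene = TRUE)),
  seed = seed)
sim <- simulate_cohort(cfg)

art <- implant_artifacts(sim$dataset, list(
  list(kind = "duplicate_sample", sample = "S00007", epsilon = 0.001),
  list(kind = "sample_missingness", sample = "S00019", rate = 0.05)),
  seed = seed + 1L)
ds <- art$dataset
set.seed(seed + 2L)
batch_snps <- order(abs(a1_freq(sim$dataset) - 0.4))[1:10]
b2 <- which(ds$samples$batch == "B2")
for (j in batch_snps) ds$genotypes[b2, j] <- rbinom(length(b2), 2L, 0.15)

write_plink(ds, file.path(out, "cohort"))
write.table(ds$samples, file.path(out, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)  # batch has no FAM slot
write_gene_ranges(sim$genes, file.path(out, "genes.tsv"))
write_gmt(sim$sets, file.path(out, "sets.gmt"))
write.table(sim$truth$causal, file.path(out, "truth_causal.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rbind(art$truth$artifacts,
                  data.frame(kind = "batch_frequency_shift",
                             id = ds$variants$rsid[batch_snps])),
            file.path(out, "truth_artifacts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
if (requireNamespace("jsonlite", quietly = TRUE))
  jsonlite::write_json(c(unclass(cfg)[setdiff(names(cfg), "causal_sets")],
                         list(causal_set = "set01", n_causal = 5, or = 1.5)),
                       file.path(out, "sim_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)

message(sprintf("cohort: %d samples x %d markers; enriched set: %s (gene %s)",
                n_samples(ds), n_variants(ds),
                sim$truth$enriched_sets,
                unique(sim$truth$causal$gene_id)))
message("wrote PLINK trio, genes.tsv, sets.gmt and truth tables under ", out)
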