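#!/usr/bin/env Rscript
# Stage 6: competitive gene-set analysis.
#
# Gene-level statistics (mean 1-df chi-square with an LD-aware
# moment-matched null, probit z), then for each set a one-sided regression
# of z on membership adjusted for gene size, length and LD, and an
# adaptive gene-label permutation correction with the family-wise
# nominal-p threshold.

library(pathgwas)

out <- file.path("results", "demo")
ds <- read_plink(file.path(out, "cohort_clean"))
genes <- read_gene_ranges(file.path(out, "genes.tsv"))
sets <- filter_gene_sets(read_gmt(file.path(out, "sets.gmt")), 10)
scan <- read.table(file.path(out, "assoc.tsv"), header = TRUE, sep = "\t")

gmap <- assign_snps_to_genes(ds$variants, genes, 10)
gs <- compute_gene_stats(ds, gmap, setNames(scan$P, scan$SNP), genes)
comp <- adaptive_permutation_correction(gs, sets, max_perm = 10000,
                                        stop_exceedances = 10, seed = 7)
write_competitive_results(gs, comp, file.path(out, "competitive"))

print(head(comp, 8), row.names = FALSE, digits = 4)
message(sprintf("permutations used: %d; family-wise nominal-p threshold at 0.05: %.4g",
                comp$N_PERM_USED[1], attr(comp, "fw_threshold")))
message("top genes by z: ",
        paste(head(gs$gene_id[order(-gs$z)], 5), collapse = ", "))
message("note: these 45 sets tile the whole simulated gene universe, so in ",
        "every gene-label permutation the strongest genes land inside some ",
        "tested set and the family-wise corrected p is very conservative; ",
        "real pathway collections cover a minority of genes")
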