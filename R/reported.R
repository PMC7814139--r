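#' Published top-SNP statistics (worked examples)
#'
#' The per-SNP summary rows (minor-allele frequencies in cases and
#' controls, single-marker p, odds ratio) reported for the top five
#' LD-independent SNPs of each of the three significant gene sets in the
#' large Tourette-syndrome case-control GWAS gene-set analysis whose
#' design this package reimplements. The underlying individual-level
#' cohort is not distributable; these printed rows serve as worked
#' examples -- in particular, the allelic odds ratio reconstructs from
#' F_A and F_U to the printed OR.
#'
#' @return data.frame with columns SET, CHR, SNP, BP, A1, F_A, F_U, A2,
#'   P, OR, GENES.
#' @export
reported_top_snps <- function() {
  read.table(system.file("extdata", "reported_top_snps.tsv",
                         package = "pathgwas"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(CHR = "character"))
}
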