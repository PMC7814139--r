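#' Genotype dataset container
#'
#' Bundles an n x m matrix of A1-allele counts with per-variant and
#' per-sample metadata. Genotypes are coded 0/1/2 copies of the A1 allele
#' (by convention the minor allele; see [orient_minor_allele()]) and `NA`
#' for a missing call -- the missing sentinel is never conflated with 0.
#'
#' @param genotypes integer matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns `chrom` (character), `rsid`
#'   (unique identifier), `bp` (1-based position), `a1`, `a2` (allele
#'   symbols, distinct).
#' @param samples data.frame with columns `sample_id` (unique), `phenotype`
#'   (`"case"`, `"control"` or `NA`), and optionally `batch` and `sex`
#'   (`"male"`, `"female"` or `NA`).
#' @param validate check invariants (dimension agreement, uniqueness,
#'   allowed codes).
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `variants`, `samples`.
#' @export
genotype_dataset <- function(genotypes, variants, samples, validate = TRUE) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(samples$batch)) samples$batch <- NA_character_
  if (is.null(samples$sex)) samples$sex <- NA_character_
  variants$chrom <- as.character(variants$chrom)
  ds <- structure(list(genotypes = genotypes, variants = variants,
                       samples = samples),
                  class = "genotype_dataset")
  if (validate) validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  g <- ds$genotypes
  if (nrow(g) != nrow(ds$samples))
    stop("genotype rows (", nrow(g), ") != samples (", nrow(ds$samples), ")")
  if (ncol(g) != nrow(ds$variants))
    stop("genotype columns (", ncol(g), ") != variants (", nrow(ds$variants), ")")
  need_v <- c("chrom", "rsid", "bp", "a1", "a2")
  if (!all(need_v %in% names(ds$variants)))
    stop("variants must have columns: ", paste(need_v, collapse = ", "))
  if (anyDuplicated(ds$variants$rsid)) stop("duplicate rsid in variants")
  if (any(ds$variants$bp < 1)) stop("bp must be >= 1")
  if (any(ds$variants$a1 == ds$variants$a2)) stop("a1 must differ from a2")
  if (anyDuplicated(ds$samples$sample_id)) stop("duplicate sample_id")
  ph <- ds$samples$phenotype
  if (!all(ph %in% c("case", "control", NA)))
    stop("phenotype must be 'case', 'control' or NA")
  bad <- !(g %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA")
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  ph <- x$samples$phenotype
  cat(sprintf("genotype_dataset: %d samples (%d cases / %d controls) x %d variants\n",
              nrow(x$samples), sum(ph == "case", na.rm = TRUE),
              sum(ph == "control", na.rm = TRUE), nrow(x$variants)))
  invisible(x)
}

#' @rdname genotype_dataset
#' @param ds a `genotype_dataset`.
#' @export
n_samples <- function(ds) nrow(ds$samples)

#' @rdname genotype_dataset
#' @export
n_variants <- function(ds) nrow(ds$variants)

#' Phenotype as 0/1 (control/case)
#' @param ds a `genotype_dataset`.
#' @return integer vector: 1 = case, 0 = control, NA = missing.
#' @export
pheno01 <- function(ds) {
  ifelse(ds$samples$phenotype == "case", 1L,
         ifelse(ds$samples$phenotype == "control", 0L, NA_integer_))
}

#' Subset a dataset by sample or variant index
#'
#' @param ds a `genotype_dataset`.
#' @param i logical or integer index.
#' @return the subsetted `genotype_dataset`.
#' @export
subset_samples <- function(ds, i) {
  genotype_dataset(ds$genotypes[i, , drop = FALSE], ds$variants,
                   ds$samples[i, , drop = FALSE], validate = FALSE)
}

#' @rdname subset_samples
#' @export
subset_variants <- function(ds, i) {
  genotype_dataset(ds$genotypes[, i, drop = FALSE],
                   ds$variants[i, , drop = FALSE], ds$samples,
                   validate = FALSE)
}

#' Per-variant A1 allele frequency on non-missing calls
#' @param ds a `genotype_dataset`.
#' @return numeric vector, length `n_variants(ds)`.
#' @export
a1_freq <- function(ds) {
  g <- ds$genotypes
  cnt <- colSums(g, na.rm = TRUE)
  called <- colSums(!is.na(g))
  ifelse(called > 0, cnt / (2 * called), NA_real_)
}

#' Orient all variants to the minor allele
#'
#' Any variant whose A1 frequency exceeds 0.5 is flipped: alleles are
#' swapped and genotypes recoded g -> 2 - g, so that A1 is the minor allele
#' everywhere (matching the F_A / F_U reporting convention).
#'
#' @param ds a `genotype_dataset`.
#' @return the re-oriented dataset; attribute `"flipped"` holds the rsids
#'   that were flipped.
#' @export
orient_minor_allele <- function(ds) {
  f <- a1_freq(ds)
  flip <- which(!is.na(f) & f > 0.5)
  if (length(flip)) {
    ds$genotypes[, flip] <- 2L - ds$genotypes[, flip]
    tmp <- ds$variants$a1[flip]
    ds$variants$a1[flip] <- ds$variants$a2[flip]
    ds$variants$a2[flip] <- tmp
  }
  attr(ds, "flipped") <- ds$variants$rsid[flip]
  ds
}

#' Mean-imputed genotype matrix
#'
#' Missing calls replaced by the per-variant mean of observed calls
#' (used for PCA, LD and the score-test fast path).
#' @param ds a `genotype_dataset`.
#' @return numeric matrix without NAs.
#' @export
impute_mean <- function(ds) {
  g <- ds$genotypes
  storage.mode(g) <- "double"
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mu[idx[, 2]]
  g[is.na(g)] <- 0  # variants with zero calls
  g
}
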