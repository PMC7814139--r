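# PLINK binary genotype IO.
#
# .bed is SNP-major with magic bytes 0x6c 0x1b 0x01; each variant is packed
# 4 samples per byte, the FIRST sample in the two LOW-order bits. Two-bit
# codes: 00 = homozygous A1 (2 copies), 01 = missing, 10 = heterozygous,
# 11 = homozygous A2 (0 copies).

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: genotype of samples 1..4 for each byte value
.bed_decode_lut <- local({
  code2geno <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  b <- 0:255
  sapply(0:3, function(s) code2geno[as.character(bitwAnd(bitwShiftR(b, 2L * s), 3L))])
})

.geno2code <- function(g) {
  # 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- integer(length(g))
  code[is.na(g)] <- 1L
  code[!is.na(g) & g == 1L] <- 2L
  code[!is.na(g) & g == 0L] <- 3L
  code
}

#' Read a PLINK binary fileset
#'
#' @param prefix path prefix (`<prefix>.bed/.bim/.fam`); alternatively give
#'   the three paths explicitly.
#' @param bed_path,bim_path,fam_path explicit file paths (override `prefix`).
#' @return a [genotype_dataset()]. FAM phenotype code 2 becomes `"case"`,
#'   1 `"control"`, 0 or -9 missing; sex 1 male, 2 female, otherwise NA.
#' @export
read_plink <- function(prefix = NULL, bed_path = NULL, bim_path = NULL,
                       fam_path = NULL) {
  if (!is.null(prefix)) {
    if (is.null(bed_path)) bed_path <- paste0(prefix, ".bed")
    if (is.null(bim_path)) bim_path <- paste0(prefix, ".bim")
    if (is.null(fam_path)) fam_path <- paste0(prefix, ".fam")
  }
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("file not found: ", f)

  if (file.size(bim_path) > 0) {
    bim <- read.table(bim_path, header = FALSE, colClasses =
                        c("character", "character", "numeric", "integer",
                          "character", "character"))
  } else {
    bim <- data.frame(V1 = character(), V2 = character(), V3 = numeric(),
                      V4 = integer(), V5 = character(), V6 = character())
  }
  names(bim) <- c("chrom", "rsid", "cm", "bp", "a1", "a2")
  fam <- read.table(fam_path, header = FALSE, colClasses =
                      c("character", "character", "character", "character",
                        "integer", "integer"))
  names(fam) <- c("fid", "iid", "pid", "mid", "sex", "pheno")
  n <- nrow(fam); m <- nrow(bim)

  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:3], .bed_magic))
    stop("malformed .bed magic bytes (not SNP-major PLINK binary): ", bed_path)
  payload <- raw[-(1:3)]
  bpv <- ceiling(n / 4)
  if (length(payload) != bpv * m)
    stop("BED payload size (", length(payload), " bytes) does not match ",
         "BIM/FAM dimensions (expected ", bpv * m, ")")

  if (m > 0 && n > 0) {
    dec <- .bed_decode_lut[as.integer(payload) + 1L, , drop = FALSE]  # (bpv*m) x 4
    arr <- array(t(dec), dim = c(4L * bpv, m))
    g <- arr[seq_len(n), , drop = FALSE]
  } else {
    g <- matrix(integer(0), nrow = n, ncol = m)
  }

  variants <- data.frame(chrom = bim$chrom, rsid = bim$rsid, bp = bim$bp,
                         a1 = bim$a1, a2 = bim$a2, stringsAsFactors = FALSE)
  phenotype <- ifelse(fam$pheno == 2L, "case",
                      ifelse(fam$pheno == 1L, "control", NA_character_))
  sex <- ifelse(fam$sex == 1L, "male",
                ifelse(fam$sex == 2L, "female", NA_character_))
  samples <- data.frame(sample_id = fam$iid, phenotype = phenotype,
                        batch = NA_character_, sex = sex,
                        stringsAsFactors = FALSE)
  genotype_dataset(g, variants, samples)
}

#' Write a PLINK binary fileset
#'
#' Lossless counterpart of [read_plink()] for genotypes, variant metadata
#' and phenotypes (the optional `batch` column has no FAM slot and is not
#' written).
#'
#' @param ds a [genotype_dataset()].
#' @param prefix output path prefix.
#' @return invisibly, the three file paths written.
#' @export
write_plink <- function(ds, prefix) {
  validate_dataset(ds)
  n <- n_samples(ds); m <- n_variants(ds)
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")

  bpv <- ceiling(n / 4)
  if (m > 0 && n > 0) {
    codes <- matrix(0L, nrow = 4L * bpv, ncol = m)  # pad bits = 00
    codes[seq_len(n), ] <- matrix(.geno2code(ds$genotypes), nrow = n)
    i1 <- seq(1L, 4L * bpv, by = 4L)
    bytes <- codes[i1, , drop = FALSE] + 4L * codes[i1 + 1L, , drop = FALSE] +
      16L * codes[i1 + 2L, , drop = FALSE] + 64L * codes[i1 + 3L, , drop = FALSE]
    payload <- as.raw(bytes)
  } else {
    payload <- raw(0)
  }
  con <- file(bed_path, "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(payload, con)

  v <- ds$variants
  write.table(data.frame(v$chrom, v$rsid, rep(0, nrow(v)),
                         format(v$bp, scientific = FALSE, trim = TRUE),
                         v$a1, v$a2),
              bim_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  s <- ds$samples
  pheno <- ifelse(is.na(s$phenotype), -9L,
                  ifelse(s$phenotype == "case", 2L, 1L))
  sex <- ifelse(is.na(s$sex), 0L, ifelse(s$sex == "male", 1L, 2L))
  write.table(data.frame(s$sample_id, s$sample_id, 0, 0, sex, pheno),
              fam_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(bed = bed_path, bim = bim_path, fam = fam_path))
}
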