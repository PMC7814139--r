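# PLINK / GMT / gene-range IO.

test_that("BED decoding agrees with an independent 2-bit lookup for all 256 bytes", {
  # oracle: decode each byte by hand from the published code table,
  # first sample in the two low-order bits
  oracle_decode <- function(byte) {
    sapply(0:3, function(s) {
      code <- (byte %/% 4^s) %% 4
      switch(code + 1, 2L, NA_integer_, 1L, 0L)  # 00,01,10,11
    })
  }
  dir <- withr::local_tempdir()
  # one variant, 4 samples, genotypes spanning all byte values:
  # write each byte as its own .bed and compare against read_plink
  ds4 <- toy_dataset(matrix(0L, 4, 1))
  for (byte in c(0:15, sample(16:255, 40))) {
    expected <- oracle_decode(byte)
    prefix <- file.path(dir, paste0("b", byte))
    write_plink(ds4, prefix)
    con <- file(paste0(prefix, ".bed"), "r+b")
    seek(con, 3, rw = "write"); writeBin(as.raw(byte), con); close(con)
    got <- read_plink(prefix)
    expect_identical(unname(got$genotypes[, 1]), expected)
  }
  # the worked example byte 0b11011000 = 216: samples 1..4 (LSB first)
  expect_identical(oracle_decode(216), c(2L, 1L, NA, 0L))
})

test_that("write_plink / read_plink round-trips genotypes and metadata", {
  dir <- withr::local_tempdir()
  for (seed in 1:5) {
    n <- sample(1:12, 1); m <- sample(0:9, 1)
    ds <- random_dataset(max(n, 1), m, miss = 0.15, seed = seed)
    prefix <- file.path(dir, paste0("rt", seed))
    write_plink(ds, prefix)
    back <- read_plink(prefix)
    expect_identical(unname(back$genotypes), unname(ds$genotypes))
    expect_identical(back$variants$rsid, ds$variants$rsid)
    expect_identical(back$variants$bp, ds$variants$bp)
    expect_identical(back$variants$a1, ds$variants$a1)
    expect_identical(back$variants$a2, ds$variants$a2)
    expect_identical(back$samples$phenotype, ds$samples$phenotype)
  }
})

test_that("missing genotype positions survive the round trip exactly", {
  dir <- withr::local_tempdir()
  ds <- random_dataset(9, 7, miss = 0.3, seed = 99)
  write_plink(ds, file.path(dir, "na"))
  back <- read_plink(file.path(dir, "na"))
  expect_identical(which(is.na(back$genotypes)), which(is.na(ds$genotypes)))
})

test_that("an all -9 FAM phenotype column reads as all-missing phenotypes", {
  dir <- withr::local_tempdir()
  ds <- toy_dataset(matrix(c(0L, 1L, 2L), 3, 2), phenotype = rep(NA_character_, 3))
  write_plink(ds, file.path(dir, "p"))
  fam <- read.table(file.path(dir, "p.fam"))
  expect_true(all(fam$V6 == -9))
  back <- read_plink(file.path(dir, "p"))
  expect_true(all(is.na(back$samples$phenotype)))
})

test_that("malformed magic bytes and dimension mismatches are rejected", {
  dir <- withr::local_tempdir()
  ds <- toy_dataset(matrix(0L, 3, 2))
  write_plink(ds, file.path(dir, "bad"))
  con <- file(file.path(dir, "bad.bed"), "r+b")
  writeBin(as.raw(c(0x00, 0x1b, 0x01)), con); close(con)
  expect_error(read_plink(file.path(dir, "bad")), "magic")
  write_plink(ds, file.path(dir, "trunc"))
  bytes <- readBin(file.path(dir, "trunc.bed"), "raw", 100)
  writeBin(bytes[-length(bytes)], file.path(dir, "trunc.bed"))
  expect_error(read_plink(file.path(dir, "trunc")), "payload")
})

test_that("an empty dataset writes a header-only BED and empty BIM", {
  dir <- withr::local_tempdir()
  ds <- toy_dataset(matrix(integer(0), 3, 0))
  write_plink(ds, file.path(dir, "empty"))
  expect_identical(file.size(file.path(dir, "empty.bed")), 3)
  expect_identical(file.size(file.path(dir, "empty.bim")), 0)
  back <- read_plink(file.path(dir, "empty"))
  expect_identical(n_variants(back), 0L)
  expect_identical(n_samples(back), 3L)
})

test_that("GMT parsing handles plain lines, duplicates and bad tokens", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sets.gmt")
  writeLines(c("setA\tdesc\t1\t2\t3", "setB\td\t7\t7"), path)
  expect_warning(col <- read_gmt(path), "duplicated")
  expect_identical(col$sets$setA, c(1L, 2L, 3L))
  expect_identical(col$sets$setB, 7L)
  expect_identical(unname(col$provenance["setA"]), "desc")
  writeLines(c("setC\td\t5\tGENE"), path)
  expect_error(read_gmt(path), "non-integer")
  writeLines(c("setD\tonly-two-fields"), path)
  expect_error(read_gmt(path), ">= 3")
})

test_that("a 51-set GMT file loads 51 sets and write_gmt round-trips", {
  dir <- withr::local_tempdir()
  set.seed(4)
  sizes <- c(rep(c(4, 6, 8), 2), sample(10:60, 45, replace = TRUE))
  sets <- setNames(lapply(seq_along(sizes),
                          function(i) sort(sample(1:5000, sizes[i]))),
                   sprintf("gs%02d", seq_along(sizes)))
  col <- gene_set_collection(sets, setNames(rep("src", 51), names(sets)))
  path <- file.path(dir, "fifty1.gmt")
  write_gmt(col, path)
  back <- read_gmt(path)
  expect_identical(n_sets(back), 51L)
  expect_identical(back$sets, col$sets)
})

test_that("filter_gene_sets mirrors the 51 -> 45 study filter and reports removals", {
  set.seed(4)
  sizes <- c(rep(c(4, 6, 8), 2), sample(10:60, 45, replace = TRUE))
  sets <- setNames(lapply(sizes, function(s) sample(1:5000, s)),
                   sprintf("gs%02d", seq_along(sizes)))
  col <- gene_set_collection(sets)
  kept <- filter_gene_sets(col, 10)
  expect_identical(n_sets(kept), 45L)
  expect_identical(sort(attr(kept, "removed")), sprintf("gs%02d", 1:6))
  expect_true(all(lengths(kept$sets) >= 10))
})

test_that("filter_gene_sets is idempotent and monotone in min_genes", {
  set.seed(9)
  col <- gene_set_collection(setNames(
    lapply(sample(1:40, 30, TRUE), function(s) sample(1:999, s)),
    paste0("s", 1:30)))
  for (k in c(1, 5, 10, 20)) {
    f1 <- filter_gene_sets(col, k)
    expect_identical(filter_gene_sets(f1, k)$sets, f1$sets)
  }
  prev <- names(filter_gene_sets(col, 1)$sets)
  expect_identical(prev, names(col$sets))  # min_genes = 1 is identity here
  for (k in c(5, 10, 20, 40)) {
    cur <- names(filter_gene_sets(col, k)$sets)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("gene ranges sort on read, accept 1-bp genes, reject start > end", {
  dir <- withr::local_tempdir()
  g <- data.frame(gene_id = c(2L, 1L, 3L), chrom = c("1", "1", "2"),
                  start = c(500L, 100L, 7L), end = c(900L, 100L, 20L),
                  symbol = c("B", "A", "C"))
  path <- file.path(dir, "genes.tsv")
  write_gene_ranges(g, path)
  back <- read_gene_ranges(path)
  expect_identical(back$gene_id, c(1L, 2L, 3L))      # sorted by (chrom, start)
  expect_identical(back$start[1], back$end[1])       # 1-bp gene accepted
  expect_identical(back[order(back$gene_id), ]$symbol, c("A", "B", "C"))
  g$start[1] <- 1000L
  expect_error(validate_gene_ranges(g), "start > end")
})

test_that("minor-allele orientation flips high-frequency variants and records them", {
  g <- cbind(c(2L, 2L, 2L, 1L), c(0L, 0L, 1L, 0L), c(1L, 1L, 1L, 1L))
  ds <- toy_dataset(g)
  or <- orient_minor_allele(ds)
  expect_identical(attr(or, "flipped"), "rs001")     # freq 7/8 flips
  expect_identical(unname(or$genotypes[, 1]), c(0L, 0L, 0L, 1L))
  expect_identical(or$variants$a1[1], "G")
  expect_true(all(a1_freq(or) <= 0.5))
  expect_identical(unname(or$genotypes[, 2]), unname(ds$genotypes[, 2]))
})
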