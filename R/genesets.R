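# Gene-set collections (GMT) and gene coordinate tables.

#' Gene-set collection
#'
#' @param sets named list of integer vectors (Entrez gene IDs); duplicates
#'   within a set are not allowed.
#' @param provenance optional named character vector of free-text source
#'   tags (defaults to empty strings).
#' @return object of class `gene_set_collection` with elements `sets` and
#'   `provenance`.
#' @export
gene_set_collection <- function(sets, provenance = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  sets <- lapply(sets, function(g) {
    g <- as.integer(g)
    if (anyDuplicated(g)) stop("duplicate gene ids within a set")
    g
  })
  if (is.null(provenance)) provenance <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, provenance = provenance[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("gene_set_collection: %d sets, %d-%d genes (median %d)\n",
              length(sz), if (length(sz)) min(sz) else 0,
              if (length(sz)) max(sz) else 0,
              if (length(sz)) as.integer(median(sz)) else 0))
  invisible(x)
}

#' @rdname gene_set_collection
#' @param collection a `gene_set_collection`.
#' @export
n_sets <- function(collection) length(collection$sets)

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: `name<TAB>description<TAB>gene1<TAB>gene2...`,
#' one set per line; gene tokens must be Entrez integers. Duplicated genes
#' within a line are removed with a warning.
#'
#' @param path file path.
#' @return a [gene_set_collection()]; descriptions become `provenance`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); prov <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, ": expected >= 3 tab-separated fields")
    genes <- suppressWarnings(as.integer(f[-(1:2)]))
    if (anyNA(genes))
      stop("GMT line ", i, " ('", f[1], "'): non-integer gene token '",
           f[-(1:2)][which(is.na(genes))[1]], "'")
    if (anyDuplicated(genes)) {
      warning("GMT line ", i, " ('", f[1], "'): duplicated gene ids removed")
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
    prov[f[1]] <- f[2]
  }
  gene_set_collection(sets, prov)
}

#' Write a GMT gene-set file
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$provenance[[nm]],
            as.character(collection$sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Drop gene sets below a minimum size
#'
#' Removes every set with fewer than `min_genes` members (default 10, the
#' conventional floor for set-based GWAS analyses).
#'
#' @param collection a [gene_set_collection()].
#' @param min_genes minimum number of genes a set must contain (>= 1).
#' @return the filtered collection; attribute `"removed"` names the sets
#'   that were dropped.
#' @export
filter_gene_sets <- function(collection, min_genes = 10) {
  stopifnot(min_genes >= 1)
  keep <- lengths(collection$sets) >= min_genes
  out <- gene_set_collection(collection$sets[keep],
                             collection$provenance[keep])
  attr(out, "removed") <- names(collection$sets)[!keep]
  out
}

#' Read a gene coordinate table
#'
#' Tab-separated, five columns: Entrez `gene_id`, `chrom`, 1-based
#' inclusive `start` and `end`, `symbol`. Returned sorted by
#' (chrom, start); overlapping genes are permitted.
#'
#' @param path file path.
#' @param header does the file carry a header line?
#' @return data.frame of gene models.
#' @export
read_gene_ranges <- function(path, header = FALSE) {
  g <- read.table(path, header = header, sep = "\t", colClasses =
                    c("integer", "character", "integer", "integer", "character"))
  names(g) <- c("gene_id", "chrom", "start", "end", "symbol")
  validate_gene_ranges(g)
}

#' @rdname read_gene_ranges
#' @param genes data.frame of gene models.
#' @export
validate_gene_ranges <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end", "symbol")
  if (!all(need %in% names(genes)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  bad <- genes$start > genes$end
  if (any(bad))
    stop("start > end for gene_id ", paste(genes$gene_id[bad], collapse = ", "))
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' @rdname read_gene_ranges
#' @export
write_gene_ranges <- function(genes, path) {
  write.table(genes[, c("gene_id", "chrom", "start", "end", "symbol")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
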