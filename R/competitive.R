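# Competitive gene-set analysis.
#
# Gene-level statistics: per-SNP 1-df chi-squares are averaged within the
# gene; the null of the mean is approximated by a scaled chi-square with
# moments matched to the LD structure (Brown-style: E[T] = 1,
# Var[T] = (2k + 4 sum_{i<j} r^2_ij) / k^2 with r the Pearson genotype
# correlation). Gene p-values are probit-transformed to z-scores and the
# competitive test regresses z on set membership plus gene-level
# covariates, one-sided for enrichment. Family-wise correction permutes
# gene labels (the competitive null is exchangeability of genes) with
# early stopping once every set has accumulated enough exceedances.

#' LD-aware gene-level statistic
#'
#' @param snp_pvalues per-SNP association p-values of the SNPs assigned to
#'   the gene.
#' @param genotype_submatrix genotype columns of those SNPs (missing
#'   entries mean-imputed for the correlation); constant columns are
#'   excluded from the correlation with a note.
#' @return list: `n_snps_param` (SNPs used), `stat` (mean chi-square),
#'   `p` (gene p from the moment-matched null), `z` (probit of 1 - p),
#'   `var_t`, `note`.
#' @export
gene_statistic <- function(snp_pvalues, genotype_submatrix) {
  k <- length(snp_pvalues)
  stopifnot(k >= 1)
  q <- qchisq(snp_pvalues, df = 1, lower.tail = FALSE)
  tstat <- mean(q)
  note <- NA_character_
  if (k == 1) {
    var_t <- 2
    p <- snp_pvalues  # exact reduction: the matched null is chi^2_1
  } else {
    G <- as.matrix(genotype_submatrix)
    mu <- colMeans(G, na.rm = TRUE)
    nas <- which(is.na(G), arr.ind = TRUE)
    if (nrow(nas)) G[nas] <- mu[nas[, 2]]
    sds <- apply(G, 2, sd)
    keep <- sds > 0
    if (!all(keep)) note <- sprintf("%d constant column(s) excluded from r",
                                    sum(!keep))
    r2sum <- if (sum(keep) >= 2) {
      cc <- cor(G[, keep, drop = FALSE])
      sum(cc[upper.tri(cc)]^2)
    } else 0
    var_t <- (2 * k + 4 * r2sum) / k^2
    # scaled chi-square with E = 1, Var = var_t:  T ~ c * chisq_f,
    # c = var_t / 2, f = 2 / var_t
    p <- pchisq(tstat * 2 / var_t, df = 2 / var_t, lower.tail = FALSE)
  }
  list(n_snps_param = k, stat = tstat, p = unname(p),
       z = qnorm(unname(p), lower.tail = FALSE), var_t = var_t, note = note)
}

#' Gene-level statistics for every gene with assigned SNPs
#'
#' @param ds a [genotype_dataset()].
#' @param gene_map [assign_snps_to_genes()] output.
#' @param snp_p named numeric vector of per-SNP p-values (names = rsids).
#' @param genes gene coordinate data.frame (for covariates).
#' @return data.frame: gene_id, chrom, start, end, n_snps_param, stat, z,
#'   p, plus the covariates log_n_snps, log_len_kb, mean_r2.
#' @export
compute_gene_stats <- function(ds, gene_map, snp_p, genes) {
  vmap <- setNames(seq_len(n_variants(ds)), ds$variants$rsid)
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- as.character(genes$gene_id[i])
    rs <- gene_map[[gid]]
    rs <- rs[rs %in% names(snp_p)]
    if (!length(rs)) next
    j <- vmap[rs]
    gs <- gene_statistic(unname(snp_p[rs]),
                         ds$genotypes[, j, drop = FALSE])
    cv <- gene_covariates(genes[i, ], ds$genotypes[, j, drop = FALSE])
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = genes$gene_id[i], chrom = genes$chrom[i],
      start = genes$start[i], end = genes$end[i],
      n_snps_param = gs$n_snps_param, stat = gs$stat, z = gs$z, p = gs$p,
      log_n_snps = cv[1], log_len_kb = cv[2], mean_r2 = cv[3],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-level covariates for the competitive regression
#'
#' (log number of assigned SNPs, log gene length in kb, mean pairwise
#' genotype r^2 -- defined as 0 for a single SNP).
#'
#' @param gene one-row gene data.frame (`start`, `end`).
#' @param assigned_snps genotype columns of the gene's SNPs.
#' @return numeric vector of length 3.
#' @export
gene_covariates <- function(gene, assigned_snps) {
  G <- as.matrix(assigned_snps)
  k <- ncol(G)
  stopifnot(k >= 1)
  len_kb <- (gene$end - gene$start + 1) / 1000
  mean_r2 <- 0
  if (k >= 2) {
    mu <- colMeans(G, na.rm = TRUE)
    nas <- which(is.na(G), arr.ind = TRUE)
    if (nrow(nas)) G[nas] <- mu[nas[, 2]]
    keep <- apply(G, 2, sd) > 0
    if (sum(keep) >= 2) {
      cc <- cor(G[, keep, drop = FALSE])
      mean_r2 <- mean(cc[upper.tri(cc)]^2)
    }
  }
  c(log_n_snps = log(k), log_len_kb = log(len_kb), mean_r2 = mean_r2)
}

#' Competitive gene-set test
#'
#' Least-squares fit z_g = alpha + beta * s_g + Gamma * C_g over all
#' analyzed genes (s = membership indicator), with a one-sided p for
#' beta > 0 from the t distribution -- enrichment means the set's genes
#' carry more association signal than the rest of the genome.
#'
#' @param gene_stats data.frame from [compute_gene_stats()] (needs `z`).
#' @param membership logical vector over genes (TRUE = in the set).
#' @param covariates numeric matrix of gene-level covariates (or NULL).
#' @return list: `set_size` (members analyzed), `n_genes_analyzed`,
#'   `beta`, `se`, `t`, `p` (one-sided), `flag`.
#' @export
competitive_set_test <- function(gene_stats, membership, covariates = NULL) {
  z <- gene_stats$z
  s <- as.numeric(membership)
  if (length(unique(s)) < 2)
    return(list(set_size = sum(s), n_genes_analyzed = length(z),
                beta = NA_real_, se = NA_real_, t = NA_real_, p = 1,
                flag = "membership_constant"))
  if (sum(s) < 2 || sum(1 - s) < 2)
    stop("need >= 2 member and >= 2 non-member genes")
  df <- if (is.null(covariates)) data.frame(z = z, s = s) else
    data.frame(z = z, s = s, covariates)
  fit <- lm(z ~ ., data = df)
  sm <- summary(fit)$coefficients
  beta <- sm["s", "Estimate"]; se <- sm["s", "Std. Error"]
  tval <- sm["s", "t value"]
  list(set_size = sum(s), n_genes_analyzed = length(z), beta = beta,
       se = se, t = tval,
       p = pt(tval, df = fit$df.residual, lower.tail = FALSE),
       flag = NA_character_)
}

# one-sided competitive p-values for all sets against one z vector,
# via Frisch-Waugh residualization (identical to lm, vectorized over sets)
.competitive_all <- function(z_res, S_res, ssq_s, df_resid) {
  beta <- as.vector(crossprod(S_res, z_res)) / ssq_s
  rss <- sum(z_res^2) - beta^2 * ssq_s
  se <- sqrt(pmax(rss, 1e-300) / (df_resid * ssq_s))
  tval <- beta / se
  list(beta = beta, t = tval,
       p = pt(tval, df = df_resid, lower.tail = FALSE))
}

#' Adaptive permutation correction for competitive set tests
#'
#' Gene z-scores are permuted against gene labels; every permutation
#' recomputes all sets' one-sided nominal p-values, and each set's
#' corrected p is (b + 1) / (R + 1) where b counts permutations whose
#' minimum nominal p across sets beats the set's observed nominal p (the
#' family-wise null). Permutation stops early once every set has
#' accumulated `stop_exceedances` exceedances, or at `max_perm`. The
#' family-wise alpha = 0.05 nominal-p threshold (5th percentile of the
#' permutation min-p distribution) is reported alongside.
#'
#' @param gene_stats data.frame from [compute_gene_stats()].
#' @param collection a [gene_set_collection()].
#' @param covariates gene-level covariate matrix aligned with
#'   `gene_stats` rows (NULL to use the three standard columns of
#'   `gene_stats`).
#' @param max_perm permutation budget (>= 100).
#' @param stop_exceedances early-stopping exceedance count (default 10).
#' @param seed RNG seed.
#' @return data.frame: SET, NGENES, BETA, P, P_CORR, N_PERM_USED;
#'   attributes `"fw_threshold"` (the alpha = 0.05 family-wise nominal-p
#'   threshold) and `"min_p_perm"` (the permutation min-p sample).
#' @export
adaptive_permutation_correction <- function(gene_stats, collection,
                                            covariates = NULL,
                                            max_perm = 10000,
                                            stop_exceedances = 10,
                                            seed = 1) {
  stopifnot(max_perm >= 100)
  if (is.null(covariates))
    covariates <- as.matrix(gene_stats[, c("log_n_snps", "log_len_kb",
                                           "mean_r2")])
  S <- n_sets(collection)
  if (max_perm < S) warning("max_perm is below the number of sets")
  z <- gene_stats$z
  Gn <- length(z)
  memb <- vapply(collection$sets,
                 function(g) gene_stats$gene_id %in% g, logical(Gn))
  ok <- colSums(memb) >= 1 & colSums(memb) < Gn
  X <- cbind(1, covariates)
  qx <- qr(X)
  S_res <- qr.resid(qx, memb * 1)
  ssq_s <- pmax(colSums(S_res^2), 1e-300)
  df_resid <- Gn - ncol(X) - 1
  z_res <- qr.resid(qx, z)
  obs <- .competitive_all(z_res, S_res, ssq_s, df_resid)
  obs$p[!ok] <- 1

  set.seed(seed)
  exceed <- integer(S)
  minp <- numeric(0)
  done <- 0L
  chunk <- 200L
  while (done < max_perm) {
    b <- as.integer(min(chunk, max_perm - done))
    Zp <- matrix(z[as.vector(vapply(seq_len(b), function(i) sample.int(Gn),
                                    integer(Gn)))], Gn, b)
    Zr <- qr.resid(qx, Zp)
    B <- crossprod(S_res, Zr) / ssq_s                    # S x b
    z2 <- colSums(Zr^2)
    RSS <- pmax(sweep(-(B^2) * ssq_s, 2, z2, "+"), 1e-300)
    Tm <- B / sqrt(RSS / (df_resid * ssq_s))
    Pm <- pt(Tm, df = df_resid, lower.tail = FALSE)
    Pm[!ok, ] <- 1
    mp <- apply(Pm, 2, min)
    minp <- c(minp, mp)
    exceed <- exceed + vapply(obs$p, function(o) sum(mp <= o), 0)
    done <- done + b
    if (min(exceed) >= stop_exceedances) break
  }
  p_corr <- (exceed + 1) / (done + 1)
  out <- data.frame(SET = names(collection$sets),
                    NGENES = colSums(memb), BETA = obs$beta, P = obs$p,
                    P_CORR = p_corr, N_PERM_USED = done,
                    stringsAsFactors = FALSE)
  out <- out[order(out$P_CORR, out$P), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fw_threshold") <- unname(quantile(minp, 0.05, type = 1))
  attr(out, "min_p_perm") <- minp
  out
}

#' Write competitive results as TSV (gene table + set table)
#' @param gene_stats data.frame from [compute_gene_stats()].
#' @param set_res data.frame from [adaptive_permutation_correction()].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_competitive_results <- function(gene_stats, set_res, prefix) {
  p1 <- paste0(prefix, "_genes.tsv")
  p2 <- paste0(prefix, "_sets.tsv")
  write.table(gene_stats[, c("gene_id", "chrom", "start", "end",
                             "n_snps_param", "stat", "z", "p")],
              p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(set_res, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
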