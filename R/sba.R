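# Self-contained set-based association (SBA) test.
#
# SNPs are assigned to genes by position (+- a genomic window), genes to
# sets; after a single-marker association pass, each set keeps its top
# LD-independent SNPs (greedy, ascending p, r^2 ceiling, capped) and the
# set statistic is the mean of their p-values. Case/control labels are
# then permuted -- covariates stay attached to their samples -- and the
# association and selection steps repeated, giving an empirical p-value
# EMP1 = (1 + #{perm stat <= observed stat}) / (n_perm + 1). A max(T)
# variant (EMP2) compares each set against the best statistic across all
# sets per permutation. Both the observed and the permutation passes use
# the Rao score test from the null logistic model, so the observed and
# permuted statistics are exchangeable under the null.

#' SBA parameters
#'
#' @param window_kb gene window in kb for SNP assignment (default 10).
#' @param set_p nominal per-SNP inclusion threshold (default 0.05).
#' @param set_r2 LD independence ceiling: a SNP enters the selection only
#'   if its r^2 with every previously selected SNP is below this
#'   (default 0.5).
#' @param set_max maximum selected SNPs per set (default 5).
#' @param n_perm number of phenotype permutations (default 10000; reaching
#'   a Bonferroni level of alpha/n_sets needs at least n_sets/alpha).
#' @param alpha family-wise level used for reporting (default 0.05).
#' @param statistic `"mean_p"` (mean of selected p-values, smaller is
#'   stronger) or `"mean_chisq"` (mean of selected 1-df chi-squares,
#'   larger is stronger).
#' @param seed RNG seed for the permutation stream.
#' @return list of class `sba_params`.
#' @export
sba_params <- function(window_kb = 10, set_p = 0.05, set_r2 = 0.5,
                       set_max = 5, n_perm = 10000, alpha = 0.05,
                       statistic = c("mean_p", "mean_chisq"), seed = 1) {
  statistic <- match.arg(statistic)
  stopifnot(window_kb >= 0, set_p > 0, set_p <= 1, set_r2 > 0, set_r2 <= 1,
            set_max >= 1, n_perm >= 1, alpha > 0, alpha < 1)
  p <- list(window_kb = window_kb, set_p = set_p, set_r2 = set_r2,
            set_max = set_max, n_perm = n_perm, alpha = alpha,
            statistic = statistic, seed = seed)
  class(p) <- "sba_params"
  p
}

#' Assign SNPs to genes by position
#'
#' A SNP belongs to a gene iff it lies on the same chromosome and within
#' `window_kb` kb of the gene body: start - W <= bp <= end + W (1-based
#' inclusive). A SNP may map to several overlapping genes.
#'
#' @param variants variant data.frame (`chrom`, `rsid`, `bp`).
#' @param genes gene data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @param window_kb window in kb (default 10).
#' @return named list: gene_id -> character vector of rsids (in position
#'   order); genes without SNPs get empty vectors.
#' @export
assign_snps_to_genes <- function(variants, genes, window_kb = 10) {
  W <- window_kb * 1000
  out <- setNames(vector("list", nrow(genes)), as.character(genes$gene_id))
  for (i in seq_along(out)) out[[i]] <- character(0)
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    vi <- which(variants$chrom == ch)
    if (!length(vi)) next
    vi <- vi[order(variants$bp[vi])]
    q <- IRanges::IRanges(start = pmax(1, genes$start[gi] - W),
                          end = genes$end[gi] + W)
    s <- IRanges::IRanges(start = variants$bp[vi], width = 1)
    ov <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (u in unique(qh)) {
      out[[as.character(genes$gene_id[gi[u]])]] <-
        variants$rsid[vi[sh[qh == u]]]
    }
  }
  out
}

#' SNP index of each gene set
#'
#' Union of the member genes' SNPs, deduplicated; empty sets are retained
#' with zero SNPs. Genes missing from the map contribute nothing.
#'
#' @param gene_map output of [assign_snps_to_genes()].
#' @param collection a [gene_set_collection()].
#' @return named list: set name -> character vector of unique rsids.
#' @export
set_snp_index <- function(gene_map, collection) {
  lapply(collection$sets, function(gids) {
    rs <- unlist(gene_map[as.character(gids)], use.names = FALSE)
    unique(rs[!is.na(rs)])
  })
}

#' Greedy LD-independent top-SNP selection
#'
#' SNPs are sorted by ascending p (ties by ascending bp, then rsid); a SNP
#' is accepted iff its p is below `set_p` and its r^2 with every
#' previously accepted SNP is below `set_r2`; selection stops at
#' `set_max`.
#'
#' @param snps character vector of rsids.
#' @param pvalues their association p-values.
#' @param genotypes genotype matrix with one column per SNP (used for
#'   r^2; missing entries mean-imputed).
#' @param params an [sba_params()].
#' @param bp optional positions for tie-breaking (defaults to input
#'   order).
#' @return selected rsids in decreasing significance.
#' @export
select_independent_top <- function(snps, pvalues, genotypes,
                                   params = sba_params(), bp = NULL) {
  if (is.null(bp)) bp <- seq_along(snps)
  ord <- order(bp, snps)
  snps <- snps[ord]; pvalues <- pvalues[ord]
  G <- as.matrix(genotypes)[, ord, drop = FALSE]
  mu <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx)) G[idx] <- mu[idx[, 2]]
  cc <- suppressWarnings(cor(G)); cc[is.na(cc)] <- 0
  st <- sba_set_stats(matrix(qchisq(pvalues, 1, lower.tail = FALSE), ncol = 1),
                      cc^2, seq_along(pvalues),
                      qchisq(params$set_p, 1, lower.tail = FALSE),
                      params$set_r2, params$set_max, TRUE)
  # replay the greedy walk to recover the identities
  cand <- order(pvalues)
  cand <- cand[pvalues[cand] < params$set_p]
  sel <- integer(0)
  for (i in cand) {
    if (length(sel) >= params$set_max) break
    if (all(cc[i, sel]^2 < params$set_r2)) sel <- c(sel, i)
  }
  stopifnot(length(sel) == st[3, 1])  # R walk must agree with the kernel
  snps[sel]
}

#' Mean-p set statistic
#'
#' @param selected_pvalues p-values of the selected SNPs (possibly empty).
#' @return their arithmetic mean; `NA` for an empty selection (the
#'   sentinel behaves as 1 in permutation comparisons).
#' @export
set_statistic <- function(selected_pvalues) {
  if (!length(selected_pvalues)) return(NA_real_)
  mean(selected_pvalues)
}

#' Bonferroni family-wise threshold
#' @param n_sets number of sets tested (>= 1).
#' @param alpha family-wise level.
#' @return `alpha / n_sets`.
#' @export
bonferroni_threshold <- function(n_sets, alpha = 0.05) {
  stopifnot(n_sets >= 1)
  alpha / n_sets
}

# score-test chi-squares for a block of phenotype vectors.
# G: imputed genotype matrix (n x u); Y: n x B matrix of 0/1 phenotypes;
# X: covariates or NULL. Fast closed form when X is NULL (the permutation
# preserves the case count, so the intercept-only null is shared).
.score_pass <- function(G, Y, X = NULL) {
  n <- nrow(G)
  if (is.null(X)) {
    ybar <- mean(Y[, 1])
    w <- ybar * (1 - ybar)
    gsum <- colSums(G)
    sgg <- colSums(G^2) - gsum^2 / n
    U <- crossprod(G, Y) - outer(gsum, colSums(Y) / n)
    V <- pmax(w * sgg, 1e-12)
    chi2 <- sweep(U^2, 1, V, "/")
    chi2[sgg <= 1e-12, ] <- 0
  } else {
    chi2 <- matrix(0, ncol(G), ncol(Y))
    for (b in seq_len(ncol(Y))) {
      chi2[, b] <- score_scan(G, Y[, b], X)$chi2
    }
  }
  chi2
}

#' Self-contained set-based association test
#'
#' @param ds a QC'd [genotype_dataset()].
#' @param collection a filtered [gene_set_collection()].
#' @param genes gene coordinate data.frame (used to build `gene_map` when
#'   not supplied).
#' @param gene_map optional precomputed [assign_snps_to_genes()] output.
#' @param covariates optional numeric matrix aligned with samples; kept
#'   attached to samples across permutations, association refit per
#'   permutation.
#' @param params an [sba_params()].
#' @param perms optional explicit n x R matrix of 0/1 phenotype
#'   assignments (one per column), e.g. the full enumeration on a tiny
#'   cohort; overrides `n_perm`/`seed`.
#' @param exclude_snps rsids removed from every set index (sensitivity
#'   re-tests).
#' @return data.frame of class `sba_result`, sorted by EMP1: SET, NSNPS,
#'   NSIG, ISIG, STAT, EMP1, EMP2 (max(T) family-wise empirical p).
#'   Attribute `"top_snps"` holds each set's selected SNPs with their
#'   per-SNP statistics; `"params"` the parameters used.
#' @export
sba_test <- function(ds, collection, genes = NULL, gene_map = NULL,
                     covariates = NULL, params = sba_params(),
                     perms = NULL, exclude_snps = NULL) {
  if (is.null(gene_map)) {
    if (is.null(genes)) stop("supply genes or gene_map")
    gene_map <- assign_snps_to_genes(ds$variants, genes, params$window_kb)
  }
  idx <- set_snp_index(gene_map, collection)
  if (!is.null(exclude_snps))
    idx <- lapply(idx, function(rs) setdiff(rs, exclude_snps))
  S <- length(idx)
  if (!S) stop("empty collection")
  if (is.null(perms)) {
    min_perm <- ceiling(S / params$alpha)
    if (params$n_perm < min_perm - 1)
      warning("n_perm = ", params$n_perm, " cannot resolve the Bonferroni ",
              "level alpha/n_sets = ", signif(params$alpha / S, 3),
              "; at least ", min_perm, " permutations are required ",
              "(1000 for 45 sets at alpha = 0.05)")
  }

  y <- pheno01(ds)
  if (anyNA(y)) stop("samples with missing phenotype must be removed first")
  mean_chisq <- params$statistic == "mean_chisq"

  # union of set SNPs, ordered by (bp, rsid) within each set for tie-breaks
  vmap <- setNames(seq_len(n_variants(ds)), ds$variants$rsid)
  set_cols <- lapply(idx, function(rs) {
    j <- vmap[rs[rs %in% names(vmap)]]
    j[order(ds$variants$bp[j], ds$variants$rsid[j])]
  })
  ucols <- sort(unique(unlist(set_cols, use.names = FALSE)))
  upos <- setNames(seq_along(ucols), ucols)
  G <- impute_mean(subset_variants(ds, ucols))

  # r^2 on the imputed genotypes: one union-level matrix, indexed per set
  Xs <- scale(G)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  R2 <- (crossprod(Xs) / (nrow(G) - 1))^2
  set_rows <- lapply(set_cols, function(j) unname(upos[as.character(j)]))
  crit <- qchisq(params$set_p, 1, lower.tail = FALSE)

  obs_chi2 <- .score_pass(G, matrix(as.numeric(y), ncol = 1), covariates)
  obs_stat <- numeric(S); nsig <- integer(S); isig <- integer(S)
  for (s in seq_len(S)) {
    if (!length(set_rows[[s]])) { obs_stat[s] <- NA; next }
    st <- sba_set_stats(obs_chi2, R2, set_rows[[s]], crit,
                        params$set_r2, params$set_max, !mean_chisq)
    obs_stat[s] <- st[1, 1]; nsig[s] <- st[2, 1]; isig[s] <- st[3, 1]
  }

  # sentinel: an empty selection behaves as the weakest possible statistic
  sent <- if (mean_chisq) 0 else 1
  obs_cmp <- ifelse(is.na(obs_stat), sent, obs_stat)

  # permutation pass, in chunks
  if (is.null(perms)) {
    R <- params$n_perm
    set.seed(params$seed)
    gen <- function(b) matrix(replicate(b, sample(as.numeric(y))), ncol = b)
  } else {
    R <- ncol(perms)
    gen <- NULL
  }
  emp1_cnt <- integer(S); emp2_cnt <- integer(S)
  done <- 0L
  chunk <- 500L
  while (done < R) {
    b <- min(chunk, R - done)
    Y <- if (is.null(perms)) gen(b) else
      matrix(as.numeric(perms[, done + seq_len(b)]), ncol = b)
    chi2 <- .score_pass(G, Y, covariates)
    stat_mat <- matrix(sent, S, b)
    for (s in seq_len(S)) {
      if (!length(set_rows[[s]])) next
      st <- sba_set_stats(chi2, R2, set_rows[[s]], crit,
                          params$set_r2, params$set_max, !mean_chisq)
      stat_mat[s, ] <- ifelse(is.na(st[1, ]), sent, st[1, ])
    }
    if (mean_chisq) {
      emp1_cnt <- emp1_cnt + rowSums(stat_mat >= obs_cmp)
      best <- apply(stat_mat, 2, max)
      emp2_cnt <- emp2_cnt + vapply(obs_cmp, function(o) sum(best >= o), 0)
    } else {
      emp1_cnt <- emp1_cnt + rowSums(stat_mat <= obs_cmp)
      best <- apply(stat_mat, 2, min)
      emp2_cnt <- emp2_cnt + vapply(obs_cmp, function(o) sum(best <= o), 0)
    }
    done <- done + b
  }
  emp1 <- (1 + emp1_cnt) / (R + 1)
  emp2 <- (1 + emp2_cnt) / (R + 1)
  emp1[is.na(obs_stat)] <- 1
  emp2[is.na(obs_stat)] <- 1

  # observed selections for reporting
  top <- vector("list", S); names(top) <- names(idx)
  for (s in seq_len(S)) {
    j <- set_cols[[s]]
    if (!length(j)) {
      top[[s]] <- data.frame(SNP = character(), CHR = character(),
                             BP = integer(), P = numeric(), F_A = numeric(),
                             F_U = numeric(), OR = numeric())
      next
    }
    rows <- set_rows[[s]]
    pv <- pchisq(obs_chi2[rows, 1], 1, lower.tail = FALSE)
    sel <- integer(0)
    cand <- order(pv)
    cand <- cand[pv[cand] < params$set_p]
    for (i in cand) {
      if (length(sel) >= params$set_max) break
      if (all(R2[rows[i], rows[sel]] < params$set_r2)) sel <- c(sel, i)
    }
    jj <- j[sel]
    fa <- fu <- or <- numeric(length(jj))
    for (t in seq_along(jj)) {
      fr <- allele_freq_by_status(ds$genotypes[, jj[t]], y)
      fa[t] <- fr$f_a; fu[t] <- fr$f_u
      or[t] <- if (fr$f_a %in% c(0, 1) || fr$f_u %in% c(0, 1)) NA_real_ else
        allelic_odds_ratio(fr$f_a, fr$f_u)
    }
    top[[s]] <- data.frame(SNP = ds$variants$rsid[jj],
                           CHR = ds$variants$chrom[jj],
                           BP = ds$variants$bp[jj], P = pv[sel],
                           F_A = fa, F_U = fu, OR = or,
                           stringsAsFactors = FALSE)
  }

  out <- data.frame(SET = names(idx), NSNPS = lengths(set_cols),
                    NSIG = nsig, ISIG = isig, STAT = obs_stat,
                    EMP1 = emp1, EMP2 = emp2, stringsAsFactors = FALSE)
  out <- out[order(out$EMP1, out$SET), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "top_snps") <- top
  attr(out, "params") <- params
  attr(out, "n_perm") <- R
  class(out) <- c("sba_result", "data.frame")
  out
}

#' max(T) family-wise empirical p-values
#'
#' Runs [sba_test()] and reports EMP2: the fraction of permutations in
#' which the best (smallest) set statistic across all sets beats the
#' focal set's observed statistic, with the (b+1)/(R+1) correction.
#'
#' @inheritParams sba_test
#' @return the `sba_result` (EMP2 column carries the max(T) p-values).
#' @export
sba_maxt <- function(ds, collection, genes = NULL, gene_map = NULL,
                     covariates = NULL, params = sba_params(),
                     perms = NULL) {
  sba_test(ds, collection, genes, gene_map, covariates, params, perms)
}

#' Sensitivity re-test of one set after dropping genes or SNPs
#'
#' Re-runs the SBA test for a single modified set, using the same
#' permutation seed so results are comparable with the original run.
#'
#' @inheritParams sba_test
#' @param set_name the focal set.
#' @param drop_genes gene_ids removed from the set (must belong to it).
#' @param drop_snps rsids removed from the set's SNP index.
#' @return one-row `sba_result` tagged with attribute `"modification"`.
#' @export
leave_out_retest <- function(ds, collection, set_name, genes = NULL,
                             gene_map = NULL, drop_genes = NULL,
                             drop_snps = NULL, covariates = NULL,
                             params = sba_params(), perms = NULL) {
  if (!set_name %in% names(collection$sets)) stop("unknown set: ", set_name)
  members <- collection$sets[[set_name]]
  if (!is.null(drop_genes) && !all(drop_genes %in% members))
    stop("drop_genes must belong to the set")
  kept <- setdiff(members, drop_genes)
  sub <- gene_set_collection(setNames(list(kept), set_name),
                             collection$provenance[set_name])
  res <- sba_test(ds, sub, genes = genes, gene_map = gene_map,
                  covariates = covariates, params = params, perms = perms,
                  exclude_snps = drop_snps)
  attr(res, "modification") <- list(set = set_name, drop_genes = drop_genes,
                                    drop_snps = drop_snps)
  res
}

#' Write SBA results as TSV (set table + long top-SNP table)
#' @param res an `sba_result`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_sba_results <- function(res, prefix) {
  p1 <- paste0(prefix, "_sets.tsv")
  p2 <- paste0(prefix, "_top_snps.tsv")
  write.table(as.data.frame(res)[, c("SET", "NSNPS", "NSIG", "ISIG",
                                     "STAT", "EMP1", "EMP2")],
              p1, sep = "\t", quote = FALSE, row.names = FALSE)
  tops <- attr(res, "top_snps")
  long <- do.call(rbind, lapply(names(tops), function(nm) {
    t <- tops[[nm]]
    if (!nrow(t)) return(NULL)
    cbind(SET = nm, t)
  }))
  if (is.null(long)) long <- data.frame(SET = character())
  write.table(long, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
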