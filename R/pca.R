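# Ancestry PCA with Patterson normalization and Tracy-Widom component
# selection, plus iterative outlier removal in PC space.

# Tracy-Widom (TW1) critical values at alpha = 0.05 / 0.01 / 0.001
.tw_crit <- c(`0.05` = 0.9793, `0.01` = 2.0234, `0.001` = 3.2724)

#' Ancestry PCA with Patterson normalization
#'
#' Missing genotypes are mean-imputed per marker and monomorphic markers
#' dropped; each marker column is centered on its mean and scaled by
#' sqrt(2*p_hat*(1-p_hat)) with the posterior allele frequency estimate
#' p_hat = (count + 0.5) / (2n + 1) (exact centering keeps the spectrum at
#' rank n-1, which the Tracy-Widom calibration relies on). Components are
#' eigenvectors of the marker-averaged sample covariance, scaled by the
#' singular values so that `scores` are the sample projections.
#'
#' @param ds a [genotype_dataset()].
#' @param K number of score columns to return (default 10).
#' @param alpha significance level for the Tracy-Widom count (0.05, 0.01
#'   or 0.001).
#' @param ld_regress residualize each standardized marker on this many
#'   preceding markers of the same chromosome before the eigenanalysis
#'   (0 = off). Linkage disequilibrium widens the noise eigenvalue bulk
#'   beyond the white-noise edge and wrecks the Tracy-Widom calibration;
#'   LD regression restores it and should be switched on (e.g. 2) whenever
#'   `n_significant` is the quantity of interest. It makes the result
#'   depend on marker order, so it is off by default for plain ancestry
#'   scores.
#' @return list of class `pca_result`: `scores` (n x K), `eigenvalues`
#'   (full non-trivial spectrum of the normalized covariance, sorted),
#'   `tw_stats`, `n_significant`, `n_markers_effective`, `trace`.
#' @export
pca_patterson <- function(ds, K = 10, alpha = 0.05, ld_regress = 0) {
  n <- n_samples(ds)
  if (n < 3) stop("PCA needs at least 3 samples")
  g <- ds$genotypes
  cnt <- colSums(g, na.rm = TRUE)
  called <- colSums(!is.na(g))
  poly <- called > 0 & cnt > 0 & cnt < 2 * called
  sub <- subset_variants(ds, which(poly))
  X <- impute_mean(sub)
  phat <- (cnt[poly] + 0.5) / (2 * called[poly] + 1)
  X <- sweep(X, 2, colMeans(X))
  X <- sweep(X, 2, sqrt(2 * phat * (1 - phat)), "/")
  if (ld_regress > 0) {
    ord <- order(sub$variants$chrom, sub$variants$bp)
    X[, ord] <- .ld_regress(X[, ord, drop = FALSE],
                            sub$variants$chrom[ord], ld_regress)
  }
  m <- ncol(X)
  C <- tcrossprod(X) / m
  ev <- eigen(C, symmetric = TRUE)
  nk <- min(n - 1, m)               # non-trivial spectrum
  lambda <- pmax(ev$values[seq_len(nk)], 0)
  K <- min(K, nk)
  scores <- ev$vectors[, seq_len(K), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(K)]), K)
  rownames(scores) <- ds$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(K))
  tw <- .tw_stats(lambda)
  nsig <- .tw_count(tw, alpha)
  structure(list(scores = scores, eigenvalues = lambda, tw_stats = tw,
                 n_significant = nsig,
                 n_markers_effective = attr(tw, "m_eff")[1],
                 eigenvalues_all = ev$values, trace = sum(diag(C))),
            class = "pca_result")
}

# residualize each standardized marker on the preceding k markers of the
# same chromosome (EIGENSOFT-style LD regression), then restore unit scale
.ld_regress <- function(X, chrom, k) {
  m <- ncol(X)
  for (j in seq_len(m)) {
    prev <- j - seq_len(min(k, j - 1))
    prev <- prev[chrom[prev] == chrom[j]]
    if (!length(prev)) next
    P <- X[, prev, drop = FALSE]
    fit <- tryCatch(qr.resid(qr(P), X[, j]), error = function(e) X[, j])
    s <- sd(fit)
    X[, j] <- if (s > 0) fit / s * sd(X[, j]) else fit
  }
  X
}

# TW statistic for each leading eigenvalue, re-estimating the effective
# marker count from the remaining spectrum at each step (moment estimator).
.tw_stats <- function(lambda, max_k = length(lambda) - 1) {
  K <- max(0, min(max_k, length(lambda) - 1))
  tw <- rep(NA_real_, K)
  meff <- rep(NA_real_, K)
  for (i in seq_len(K)) {
    lam <- lambda[i:length(lambda)]
    L <- length(lam)
    s1 <- sum(lam); s2 <- sum(lam^2)
    den <- L * s2 - s1^2
    if (den <= 0 || s1 <= 0) break
    me <- ((L + 1) * s1^2) / den
    ell <- L * lam[1] / s1
    mu <- (sqrt(me - 1) + sqrt(L))^2 / me
    sig <- (sqrt(me - 1) + sqrt(L)) / me *
      (1 / sqrt(me - 1) + 1 / sqrt(L))^(1 / 3)
    tw[i] <- (ell - mu) / sig
    meff[i] <- me
  }
  attr(tw, "m_eff") <- meff
  tw
}

#' Count significant principal components (Tracy-Widom)
#'
#' Patterson's procedure: leading eigenvalues are standardized to
#' Tracy-Widom statistics using the effective marker count estimated from
#' eigenvalue moments, and compared to the TW1 critical value; components
#' are counted significant until the first failure.
#'
#' @param eigenvalues eigenvalue spectrum from [pca_patterson()].
#' @param alpha 0.05 (default), 0.01 or 0.001.
#' @return number of significant components.
#' @export
tracy_widom_significant <- function(eigenvalues, alpha = 0.05) {
  if (length(eigenvalues) < 2) stop("need at least 2 eigenvalues")
  .tw_count(.tw_stats(eigenvalues), alpha)
}

.tw_count <- function(tw, alpha) {
  crit <- .tw_crit[as.character(alpha)]
  if (is.na(crit)) stop("alpha must be one of 0.05, 0.01, 0.001")
  sig <- !is.na(tw) & tw > crit
  if (!length(sig) || !sig[1]) return(0L)
  r <- rle(sig)
  as.integer(r$lengths[1])
}

#' Iterative PCA outlier removal
#'
#' Recompute ancestry PCA and remove every sample lying beyond `sd_limit`
#' standard deviations from the mean on any of the top `n_pcs` components;
#' repeat until a round removes nobody or `max_rounds` is reached.
#'
#' @param ds a [genotype_dataset()].
#' @param sd_limit SD threshold (default 6).
#' @param n_pcs components scanned (default 10).
#' @param max_rounds maximum iterations (default 5).
#' @return list(`dataset`, `removed`) with removed sample_ids in removal
#'   order.
#' @export
pca_outlier_removal <- function(ds, sd_limit = 6, n_pcs = 10, max_rounds = 5) {
  stopifnot(sd_limit > 0)
  removed <- character(0)
  if (!is.finite(sd_limit)) return(list(dataset = ds, removed = removed))
  for (round in seq_len(max_rounds)) {
    k <- min(n_pcs, n_samples(ds) - 2)
    if (k < 1) break
    pc <- pca_patterson(ds, K = k)
    sc <- scale(pc$scores)           # center and SD-normalize each PC
    out <- which(apply(abs(sc) > sd_limit, 1, any))
    if (!length(out)) break
    if (n_samples(ds) - length(out) < 3)
      stop("PCA outlier removal would leave fewer than 3 samples")
    removed <- c(removed, ds$samples$sample_id[out])
    ds <- subset_samples(ds, -out)
  }
  list(dataset = ds, removed = removed)
}

#' Write PC scores and the eigenvalue / Tracy-Widom table as TSV
#' @param pca a `pca_result`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_pca_result <- function(pca, prefix) {
  p1 <- paste0(prefix, "_scores.tsv")
  p2 <- paste0(prefix, "_eigen.tsv")
  write.table(data.frame(sample_id = rownames(pca$scores), pca$scores),
              p1, sep = "\t", quote = FALSE, row.names = FALSE)
  k <- length(pca$tw_stats)
  write.table(data.frame(component = seq_len(k),
                         eigenvalue = pca$eigenvalues[seq_len(k)],
                         tw_stat = pca$tw_stats,
                         significant_at_0.05 = !is.na(pca$tw_stats) &
                           pca$tw_stats > .tw_crit[["0.05"]]),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
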