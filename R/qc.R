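# Sample and marker quality control.
#
# The cascade mirrors standard case-control GWAS practice: sample call
# rate and inbreeding first, then marker call rate, case-control
# differential missingness and Hardy-Weinberg exact tests (separately in
# controls and cases, at different stringencies), pairwise batch-effect
# scans, ancestry-PCA outlier removal, and identity-by-descent relatedness
# pruning.

#' Default QC thresholds
#'
#' @param sample_call_rate minimum per-sample call rate (0.98).
#' @param inbreeding_abs_max maximum |F| method-of-moments inbreeding
#'   coefficient (0.2; both excess homozygosity and heterozygosity flag
#'   artifacts).
#' @param marker_call_rate minimum per-marker call rate (0.98).
#' @param diff_missingness_max maximum absolute case-control missingness
#'   rate difference (0.02).
#' @param hwe_p_controls,hwe_p_cases HWE exact-test p-value floors in
#'   controls (1e-6) and cases (1e-10).
#' @param batch_p_max flag a marker if any pairwise batch test (allelic
#'   association or missingness, within cases only and controls only)
#'   attains p at or below this (1e-6).
#' @param pihat_max PI_HAT relatedness ceiling (0.1875, halfway between
#'   second- and third-degree relatives).
#' @param pca_outlier_sd remove samples beyond this many SDs on any of the
#'   leading ancestry PCs (6).
#' @param pca_n_pcs number of PCs scanned for outliers (10).
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_call_rate = 0.98, inbreeding_abs_max = 0.2,
                          marker_call_rate = 0.98, diff_missingness_max = 0.02,
                          hwe_p_controls = 1e-6, hwe_p_cases = 1e-10,
                          batch_p_max = 1e-6, pihat_max = 0.1875,
                          pca_outlier_sd = 6, pca_n_pcs = 10) {
  th <- as.list(environment())
  class(th) <- "qc_thresholds"
  th
}

#' Per-sample call rates
#' @param ds a [genotype_dataset()].
#' @return numeric vector in `[0, 1]`, fraction of non-missing genotypes.
#' @export
sample_call_rates <- function(ds) {
  stopifnot(n_variants(ds) >= 1)
  rowMeans(!is.na(ds$genotypes))
}

#' Per-marker call rates
#' @param ds a [genotype_dataset()].
#' @return numeric vector in `[0, 1]`.
#' @export
marker_call_rates <- function(ds) colMeans(!is.na(ds$genotypes))

#' Method-of-moments inbreeding coefficient per sample
#'
#' F = (O_hom - E_hom) / (L - E_hom), where O_hom counts observed
#' homozygous calls over the sample's non-missing polymorphic markers and
#' E_hom sums the sample-size-corrected expected homozygosity
#' 1 - 2 p q * A/(A - 1) (A = number of called alleles at the marker).
#' Monomorphic markers are excluded.
#'
#' @param ds a [genotype_dataset()].
#' @return numeric vector of F; NA (with a warning) where no polymorphic
#'   marker is callable.
#' @export
inbreeding_coefficient <- function(ds) {
  g <- ds$genotypes
  called <- colSums(!is.na(g))
  p <- a1_freq(ds)
  A <- 2 * called
  poly <- !is.na(p) & p > 0 & p < 1 & A > 1
  exp_het <- 2 * p * (1 - p) * A / (A - 1)
  gp <- g[, poly, drop = FALSE]
  obs <- !is.na(gp)
  o_hom <- rowSums(gp != 1L, na.rm = TRUE)
  e_hom <- as.vector(obs %*% (1 - exp_het[poly]))
  L <- rowSums(obs)
  f <- (o_hom - e_hom) / (L - e_hom)
  f[L == 0] <- NA_real_
  if (anyNA(f)) warning("inbreeding F undefined for ", sum(is.na(f)),
                        " sample(s) with no callable polymorphic marker")
  f
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the genotype counts, the p-value is the
#' total probability of all heterozygote counts (conditional on the allele
#' counts) no more probable than the observed one.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (A1 homozygote,
#'   heterozygote, A2 homozygote); vectors are accepted and recycled.
#' @return p-value(s) in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  if (any(c(n_hom1, n_het, n_hom2) < 0)) stop("negative genotype counts")
  mapply(.hwe_exact_one, n_hom1, n_het, n_hom2)
}

.hwe_exact_one <- function(h1, het, h2) {
  n <- h1 + het + h2
  if (n < 1) stop("total genotype count must be >= 1")
  na <- 2 * h1 + het          # A1 allele count
  rare <- min(na, 2 * n - na)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)  # feasible heterozygote counts
  hom_r <- (rare - hs) / 2
  hom_c <- n - hs - hom_r
  logp <- lfactorial(n) - lfactorial(hom_r) - lfactorial(hs) -
    lfactorial(hom_c) + hs * log(2) + lfactorial(rare) +
    lfactorial(2 * n - rare) - lfactorial(2 * n)
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[match(het, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Case-control differential missingness at one marker
#'
#' The primary filter quantity is the absolute difference in missingness
#' rates between cases and controls; a 2x2 chi-square on
#' missing/called x case/control is reported alongside.
#'
#' @param ds a [genotype_dataset()].
#' @param rsid marker identifier.
#' @return list with `diff` (absolute rate difference), `p_chisq`,
#'   `miss_case`, `miss_control`.
#' @export
differential_missingness_test <- function(ds, rsid) {
  j <- match(rsid, ds$variants$rsid)
  if (is.na(j)) stop("unknown rsid: ", rsid)
  y <- pheno01(ds)
  if (!any(y == 1L, na.rm = TRUE) || !any(y == 0L, na.rm = TRUE))
    stop("both phenotype classes must be present")
  miss <- is.na(ds$genotypes[, j])
  mc <- mean(miss[y == 1L & !is.na(y)])
  mu <- mean(miss[y == 0L & !is.na(y)])
  tab <- table(factor(miss, c(FALSE, TRUE)), factor(y, 0:1))
  p <- .chisq2x2(tab)
  list(diff = abs(mc - mu), p_chisq = p, miss_case = mc, miss_control = mu)
}

# 2x2 Pearson chi-square without continuity correction; p = 1 on degenerate margins
.chisq2x2 <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stat <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  if (!is.finite(stat)) return(1)
  unname(pchisq(stat, 1, lower.tail = FALSE))
}

# vectorized 2x2 chi-square from count vectors
.chisq2x2_vec <- function(a, b, c, d) {
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    pmax((a + b) * (c + d) * (a + c) * (b + d), 1e-300)
  p <- pchisq(stat, 1, lower.tail = FALSE)
  p[(a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0] <- 1
  p
}

#' Pairwise batch-effect scan
#'
#' For every pair of genotyping batches and within each phenotype stratum
#' (cases only, controls only), tests each marker for allelic association
#' between batches and for differential missingness between batches
#' (2x2 chi-squares). A marker is flagged if any of these p-values falls
#' at or below `p_max`.
#'
#' @param ds a [genotype_dataset()].
#' @param p_max flagging threshold (default 1e-6).
#' @return data.frame (rsid, min_p, flagged); with a single batch, a no-op
#'   with a warning (min_p = 1).
#' @export
batch_effect_scan <- function(ds, p_max = 1e-6) {
  batches <- sort(unique(ds$samples$batch))
  out <- data.frame(rsid = ds$variants$rsid, min_p = 1, flagged = FALSE,
                    stringsAsFactors = FALSE)
  if (length(batches) < 2) {
    warning("single batch: batch-effect scan is a no-op")
    return(out)
  }
  y <- pheno01(ds)
  minp <- rep(1, n_variants(ds))
  for (i in seq_len(length(batches) - 1)) for (j in (i + 1):length(batches)) {
    for (cls in c(1L, 0L)) {
      r1 <- which(ds$samples$batch == batches[i] & y == cls)
      r2 <- which(ds$samples$batch == batches[j] & y == cls)
      if (!length(r1) || !length(r2)) next
      g1 <- ds$genotypes[r1, , drop = FALSE]
      g2 <- ds$genotypes[r2, , drop = FALSE]
      c1 <- colSums(!is.na(g1)); c2 <- colSums(!is.na(g2))
      # allelic association between batches
      a1 <- colSums(g1, na.rm = TRUE); a2c <- colSums(g2, na.rm = TRUE)
      p_assoc <- .chisq2x2_vec(a1, 2 * c1 - a1, a2c, 2 * c2 - a2c)
      # missingness between batches
      m1 <- nrow(g1) - c1; m2 <- nrow(g2) - c2
      p_miss <- .chisq2x2_vec(m1, c1, m2, c2)
      minp <- pmin(minp, p_assoc, p_miss)
    }
  }
  out$min_p <- minp
  out$flagged <- minp <= p_max
  out
}

# Expected IBS probabilities given IBD state, averaged over markers.
# Allele-frequency functionals (p^2q^2, p^3q, ...) are estimated by
# unbiased factorial moments of the allele counts -- the plug-in p-hat
# versions are visibly biased at desk-scale marker/sample counts and
# inflate PI_HAT for unrelated pairs.
.ibd_expectations <- function(ds) {
  g <- ds$genotypes
  a <- colSums(g, na.rm = TRUE)            # A1 allele count
  T2 <- 2 * colSums(!is.na(g))             # called alleles
  use <- a > 0 & a < T2 & T2 >= 4
  a <- a[use]; T2 <- T2[use]
  b <- T2 - a
  ff <- function(x, k) {
    out <- x
    for (i in seq_len(k - 1)) out <- out * (x - i)
    out
  }
  list(
    use = use,
    e0_z0 = mean(2 * ff(a, 2) * ff(b, 2) / ff(T2, 4)),
    e1_z0 = mean(4 * (ff(a, 3) * b + a * ff(b, 3)) / ff(T2, 4)),
    e2_z0 = mean((ff(a, 4) + ff(b, 4) + 4 * ff(a, 2) * ff(b, 2)) / ff(T2, 4)),
    e1_z1 = mean(2 * (ff(a, 2) * b + a * ff(b, 2)) / ff(T2, 3)),
    e2_z1 = mean((ff(a, 3) + ff(b, 3) + ff(a, 2) * b + a * ff(b, 2)) /
                   ff(T2, 3)))
}

# method-of-moments IBD for all sample pairs (Purcell-style).
# Returns a list of n x n matrices: pihat and shared (marker counts).
.ibd_pihat_all <- function(ds) {
  ex <- .ibd_expectations(ds)
  g <- ds$genotypes[, ex$use, drop = FALSE]
  I0 <- (!is.na(g) & g == 0L) * 1; I1 <- (!is.na(g) & g == 1L) * 1
  I2 <- (!is.na(g) & g == 2L) * 1
  M <- (!is.na(g)) * 1
  ibs0 <- tcrossprod(I0, I2); ibs0 <- ibs0 + t(ibs0)
  ibs2 <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2)
  shared <- tcrossprod(M)
  ibs1 <- shared - ibs0 - ibs2
  e0_z0 <- ex$e0_z0; e1_z0 <- ex$e1_z0; e2_z0 <- ex$e2_z0
  e1_z1 <- ex$e1_z1; e2_z1 <- ex$e2_z1
  z0 <- ibs0 / (shared * e0_z0)
  z1 <- (ibs1 / shared - e1_z0 * z0) / e1_z1
  z2 <- (ibs2 / shared - e2_z0 * z0 - e2_z1 * z1)
  # clamp only the final quantity: clamping the state estimates first
  # biases PI_HAT upward for unrelated pairs
  pihat <- pmin(pmax((z2 + 0.5 * z1) / (z0 + z1 + z2), 0), 1)
  diag(pihat) <- 1
  list(pihat = pihat, shared = shared)
}

#' PI_HAT identity-by-descent estimate for one sample pair
#'
#' Method-of-moments estimation from identity-by-state sharing counts and
#' allele frequencies; PI_HAT = P(IBD=2) + P(IBD=1)/2, clamped to [0, 1].
#' An LD-pruned marker set is recommended (see [ld_prune()]).
#'
#' @param ds a [genotype_dataset()].
#' @param pair character vector of two sample_ids (or integer indices).
#' @return PI_HAT; attribute `"unreliable"` is TRUE when fewer than 50
#'   overlapping called markers support the estimate.
#' @export
ibd_pihat <- function(ds, pair) {
  idx <- if (is.character(pair)) match(pair, ds$samples$sample_id) else pair
  stopifnot(length(idx) == 2, !anyNA(idx))
  ex <- .ibd_expectations(ds)  # frequencies from the full dataset
  g1 <- ds$genotypes[idx[1], ex$use]; g2 <- ds$genotypes[idx[2], ex$use]
  use <- !is.na(g1) & !is.na(g2)
  shared <- sum(use)
  g1 <- g1[use]; g2 <- g2[use]
  ibs0 <- sum(abs(g1 - g2) == 2L); ibs2 <- sum(g1 == g2)
  ibs1 <- shared - ibs0 - ibs2
  e0_z0 <- ex$e0_z0; e1_z0 <- ex$e1_z0; e2_z0 <- ex$e2_z0
  e1_z1 <- ex$e1_z1; e2_z1 <- ex$e2_z1
  z0 <- ibs0 / (shared * e0_z0)
  z1 <- (ibs1 / shared - e1_z0 * z0) / e1_z1
  z2 <- ibs2 / shared - e2_z0 * z0 - e2_z1 * z1
  ph <- min(max((z2 + 0.5 * z1) / (z0 + z1 + z2), 0), 1)
  attr(ph, "unreliable") <- shared < 50
  if (shared < 50)
    warning("PI_HAT based on < 50 overlapping called markers")
  ph
}

#' Greedy LD pruning
#'
#' Windowed greedy r^2 pruning on mean-imputed genotypes: within sliding
#' windows, the later member of any pair with r^2 >= `r2_max` is dropped.
#'
#' @param ds a [genotype_dataset()].
#' @param r2_max r^2 ceiling (default 0.2).
#' @param window window size in SNPs (default 50).
#' @return integer indices of retained variants.
#' @export
ld_prune <- function(ds, r2_max = 0.2, window = 50) {
  X <- impute_mean(ds)
  m <- ncol(X)
  keep <- rep(TRUE, m)
  starts <- seq(1, m, by = max(1, window %/% 2))
  for (s in starts) {
    cols <- s:min(s + window - 1, m)
    cols <- cols[keep[cols]]
    if (length(cols) < 2) next
    cc <- suppressWarnings(cor(X[, cols, drop = FALSE]))
    cc[is.na(cc)] <- 0
    r2 <- cc^2
    for (a in seq_along(cols)) {
      if (!keep[cols[a]]) next
      later <- which(r2[a, ] >= r2_max)
      later <- later[later > a]
      keep[cols[later]] <- FALSE
    }
  }
  which(keep)
}

#' Run the full QC cascade
#'
#' Stage order: sample call rate, |F| inbreeding, marker call rate,
#' case-control differential missingness, HWE (controls then cases),
#' pairwise batch-effect scan, ancestry-PCA outlier removal, IBD
#' relatedness pruning. Relatedness is resolved by removing the member of
#' each flagged pair with the lower call rate (ties: lexicographically
#' larger sample_id).
#'
#' @param ds a [genotype_dataset()].
#' @param thresholds a [qc_thresholds()].
#' @param do_pca run the PCA outlier stage (needs >= 10 samples).
#' @return list(`dataset`, `report`); the report holds `removed_samples`,
#'   `removed_markers` (with single reasons) and per-stage `counts`.
#' @export
run_qc <- function(ds, thresholds = qc_thresholds(), do_pca = TRUE) {
  th <- thresholds
  rs <- data.frame(sample_id = character(), reason = character(),
                   stringsAsFactors = FALSE)
  rm_ <- data.frame(rsid = character(), reason = character(),
                    stringsAsFactors = FALSE)
  counts <- list()
  note <- function(stage, ds) {
    counts[[length(counts) + 1]] <<- data.frame(
      stage = stage, samples = n_samples(ds), markers = n_variants(ds))
  }
  note("input", ds)

  drop_samples <- function(ds, idx, reason) {
    if (!length(idx)) return(ds)
    rs <<- rbind(rs, data.frame(sample_id = ds$samples$sample_id[idx],
                                reason = reason))
    subset_samples(ds, -idx)
  }
  drop_markers <- function(ds, idx, reason) {
    if (!length(idx)) return(ds)
    rm_ <<- rbind(rm_, data.frame(rsid = ds$variants$rsid[idx],
                                  reason = reason))
    subset_variants(ds, -idx)
  }

  # 1. sample call rate
  ds <- drop_samples(ds, which(sample_call_rates(ds) < th$sample_call_rate),
                     "low_call_rate")
  if (n_samples(ds) == 0) stop("all samples removed by QC")
  note("sample_call_rate", ds)

  # 2. inbreeding |F|
  f <- suppressWarnings(inbreeding_coefficient(ds))
  ds <- drop_samples(ds, which(!is.na(f) & abs(f) > th$inbreeding_abs_max),
                     "inbreeding")
  note("inbreeding", ds)

  # 3. marker call rate
  ds <- drop_markers(ds, which(marker_call_rates(ds) < th$marker_call_rate),
                     "marker_call_rate")
  note("marker_call_rate", ds)

  # 4. differential missingness (rate difference)
  y <- pheno01(ds)
  miss <- is.na(ds$genotypes)
  if (any(y == 1L, na.rm = TRUE) && any(y == 0L, na.rm = TRUE)) {
    dmiss <- abs(colMeans(miss[which(y == 1L), , drop = FALSE]) -
                 colMeans(miss[which(y == 0L), , drop = FALSE]))
    ds <- drop_markers(ds, which(dmiss > th$diff_missingness_max),
                       "differential_missingness")
  }
  note("differential_missingness", ds)

  # 5. HWE in controls then cases
  for (cls in c("control", "case")) {
    rows <- which(ds$samples$phenotype == cls)
    if (!length(rows)) next
    gg <- ds$genotypes[rows, , drop = FALSE]
    h1 <- colSums(gg == 2L, na.rm = TRUE)
    he <- colSums(gg == 1L, na.rm = TRUE)
    h2 <- colSums(gg == 0L, na.rm = TRUE)
    ok <- (h1 + he + h2) >= 1
    pv <- rep(1, ncol(gg))
    pv[ok] <- hwe_exact_test(h1[ok], he[ok], h2[ok])
    lim <- if (cls == "control") th$hwe_p_controls else th$hwe_p_cases
    ds <- drop_markers(ds, which(pv < lim),
                       if (cls == "control") "hwe_controls" else "hwe_cases")
  }
  note("hwe", ds)

  # 6. batch-effect scan
  if (length(unique(ds$samples$batch)) >= 2) {
    bs <- batch_effect_scan(ds, th$batch_p_max)
    ds <- drop_markers(ds, which(bs$flagged), "batch_effect")
  }
  note("batch_scan", ds)

  # 7. PCA ancestry outliers
  if (do_pca && is.finite(th$pca_outlier_sd) && n_samples(ds) >= 10) {
    pr <- pca_outlier_removal(ds, sd_limit = th$pca_outlier_sd,
                              n_pcs = min(th$pca_n_pcs, n_samples(ds) - 2))
    if (length(pr$removed)) {
      idx <- match(pr$removed, ds$samples$sample_id)
      ds <- drop_samples(ds, idx, "pca_outlier")
    }
  }
  note("pca_outliers", ds)

  # 8. IBD relatedness pruning on an LD-pruned marker subset
  if (n_samples(ds) >= 2 && n_variants(ds) >= 2) {
    pruned <- ld_prune(ds)
    sub <- subset_variants(ds, pruned)
    ib <- .ibd_pihat_all(sub)
    ph <- ib$pihat
    ph[ib$shared < 50] <- 0
    cr <- sample_call_rates(ds)
    flagged <- which(upper.tri(ph) & ph > th$pihat_max, arr.ind = TRUE)
    to_drop <- integer(0)
    if (nrow(flagged)) {
      ord <- order(-ph[flagged])
      for (k in ord) {
        i <- flagged[k, 1]; j <- flagged[k, 2]
        if (i %in% to_drop || j %in% to_drop) next
        pick <- if (cr[i] < cr[j]) i else if (cr[j] < cr[i]) j else {
          if (ds$samples$sample_id[i] > ds$samples$sample_id[j]) i else j
        }
        to_drop <- c(to_drop, pick)
      }
    }
    ds <- drop_samples(ds, to_drop, "relatedness")
  }
  note("relatedness", ds)

  report <- list(removed_samples = rs, removed_markers = rm_,
                 counts = do.call(rbind, counts), thresholds = th)
  class(report) <- "qc_report"
  list(dataset = ds, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  print(x$counts, row.names = FALSE)
  if (nrow(x$removed_samples)) {
    cat("removed samples by reason:\n")
    print(table(x$removed_samples$reason))
  }
  if (nrow(x$removed_markers)) {
    cat("removed markers by reason:\n")
    print(table(x$removed_markers$reason))
  }
  invisible(x)
}

#' Write a QC report as TSV files
#' @param report a `qc_report`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_qc_report <- function(report, prefix) {
  ps <- paste0(prefix, c("_removed_samples.tsv", "_removed_markers.tsv",
                         "_counts.tsv"))
  write.table(report$removed_samples, ps[1], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$removed_markers, ps[2], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$counts, ps[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(ps)
}
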