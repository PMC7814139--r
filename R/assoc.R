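# Covariate-adjusted single-marker association.
#
# Reporting path: per-SNP logistic regression (additive coding, Wald test).
# Fast path: Rao score test from the null model (covariates only), which
# needs one null fit per phenotype vector and pure matrix algebra per SNP
# -- the workhorse of the permutation loops in the set-based test.

#' Fit the logistic association model for one SNP
#'
#' logit P(case) = b0 + b_g * g + Gamma * covariates, additive genotype
#' coding (0/1/2 A1 copies); samples with a missing genotype are dropped
#' for that SNP (complete-case). On separation or non-convergence the SNP
#' is flagged and p is set to 1 with a reason code.
#'
#' @param genotype_column integer vector of A1 counts (NA = missing).
#' @param phenotype 0/1 vector (1 = case).
#' @param covariates optional numeric matrix (e.g. PC scores).
#' @return list: `beta`, `se`, `p` (two-sided Wald), `or_`, `f_a`, `f_u`,
#'   `n_used`, `flag` (NA when clean; otherwise `"monomorphic"`,
#'   `"separation"`, `"not_converged"` or `"collinear"`).
#' @export
fit_logistic_snp <- function(genotype_column, phenotype, covariates = NULL) {
  g <- as.numeric(genotype_column)
  y <- as.numeric(phenotype)
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  use <- !is.na(g) & !is.na(y)
  if (!is.null(X)) use <- use & !rowSums(is.na(X))
  g <- g[use]; y <- y[use]
  if (!is.null(X)) X <- X[use, , drop = FALSE]
  fr <- allele_freq_by_status(genotype_column, phenotype)
  out <- list(beta = NA_real_, se = NA_real_, p = 1, or_ = NA_real_,
              f_a = fr$f_a, f_u = fr$f_u, n_used = length(y), flag = NA_character_)
  if (length(unique(g)) < 2) {
    out$flag <- "monomorphic"
    return(out)
  }
  M <- cbind(`(Intercept)` = 1, g = g, X)
  if (qr(M)$rank < ncol(M)) {
    out$flag <- "collinear"
    return(out)
  }
  fit <- suppressWarnings(glm.fit(M, y, family = binomial()))
  beta <- fit$coefficients["g"]
  R <- qr.R(fit$qr)
  cov <- tryCatch(chol2inv(R), error = function(e) NULL)
  se <- if (is.null(cov)) NA_real_ else {
    # glm.fit pivots; map back to coefficient order
    piv <- fit$qr$pivot
    sqrt(diag(cov))[match(2L, piv)]
  }
  if (!fit$converged) {
    out$flag <- "not_converged"
    return(out)
  }
  if (is.na(se) || !is.finite(se) || abs(beta) > 15 || se > 100) {
    out$flag <- "separation"
    return(out)
  }
  z <- beta / se
  out$beta <- unname(beta); out$se <- se
  out$p <- 2 * pnorm(-abs(z))
  out$or_ <- exp(unname(beta))
  out
}

#' A1 allele frequency by case/control status
#'
#' frequency = A1 allele count / (2 x called samples), per class.
#'
#' @param genotype_column integer vector of A1 counts.
#' @param phenotype 0/1 vector (1 = case).
#' @return list(`f_a` = cases, `f_u` = controls); NA for an empty class.
#' @export
allele_freq_by_status <- function(genotype_column, phenotype) {
  g <- as.numeric(genotype_column)
  y <- as.numeric(phenotype)
  f1 <- function(gg) {
    gg <- gg[!is.na(gg)]
    if (!length(gg)) return(NA_real_)
    sum(gg) / (2 * length(gg))
  }
  list(f_a = f1(g[!is.na(y) & y == 1]), f_u = f1(g[!is.na(y) & y == 0]))
}

#' Allelic odds ratio from minor-allele frequencies
#'
#' OR = (f_a / (1 - f_a)) / (f_u / (1 - f_u)).
#'
#' @param f_a,f_u minor-allele frequencies in cases and controls.
#' @return the odds ratio; boundary frequencies give 0 or Inf with a
#'   warning.
#' @export
allelic_odds_ratio <- function(f_a, f_u) {
  if (any(f_a < 0 | f_a > 1 | f_u < 0 | f_u > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  if (any(f_a %in% c(0, 1) | f_u %in% c(0, 1)))
    warning("boundary frequency: odds ratio is 0 or infinite")
  (f_a / (1 - f_a)) / (f_u / (1 - f_u))
}

#' Genome-wide single-marker association scan
#'
#' One covariate-adjusted logistic fit per retained SNP (see
#' [fit_logistic_snp()]); deterministic given its inputs and invariant to
#' sample ordering.
#'
#' @param ds a QC'd [genotype_dataset()].
#' @param covariates optional numeric matrix aligned with samples (e.g.
#'   the first PCs).
#' @return data.frame with one row per SNP: CHR, SNP, BP, A1, A2, F_A,
#'   F_U, N, BETA, SE, P, OR, FLAG.
#' @export
gwas_scan <- function(ds, covariates = NULL) {
  y <- pheno01(ds)
  m <- n_variants(ds)
  res <- vector("list", m)
  for (j in seq_len(m)) {
    f <- fit_logistic_snp(ds$genotypes[, j], y, covariates)
    res[[j]] <- data.frame(
      CHR = ds$variants$chrom[j], SNP = ds$variants$rsid[j],
      BP = ds$variants$bp[j], A1 = ds$variants$a1[j],
      A2 = ds$variants$a2[j], F_A = f$f_a, F_U = f$f_u, N = f$n_used,
      BETA = f$beta, SE = f$se, P = f$p, OR = f$or_, FLAG = f$flag,
      stringsAsFactors = FALSE)
  }
  out <- if (m) do.call(rbind, res) else
    data.frame(CHR = character(), SNP = character(), BP = integer(),
               A1 = character(), A2 = character(), F_A = numeric(),
               F_U = numeric(), N = integer(), BETA = numeric(),
               SE = numeric(), P = numeric(), OR = numeric(),
               FLAG = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rao score test association scan
#'
#' Fits the null logistic model (covariates only) once, then computes the
#' 1-df score chi-square for adding each genotype column. Missing
#' genotypes are mean-imputed. Used for the permutation fast path; agrees
#' asymptotically with the Wald scan.
#'
#' @param G numeric genotype matrix (no NAs; see [impute_mean()]).
#' @param y 0/1 phenotype vector.
#' @param covariates optional numeric covariate matrix.
#' @return list: `chi2`, `p` (vectors over columns of G).
#' @export
score_scan <- function(G, y, covariates = NULL) {
  X <- cbind(rep(1, length(y)), covariates)
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  U <- as.vector(crossprod(G, y - mu))
  XtWX <- crossprod(X * w, X)
  A <- crossprod(X * w, G)                  # k x m
  V <- as.vector(crossprod(G^2, w)) - colSums(A * solve(XtWX, A))
  chi2 <- ifelse(V > 1e-12, U^2 / V, 0)
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Write association results as a tab-separated table
#' @param scan result of [gwas_scan()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_assoc_results <- function(scan, path) {
  cols <- c("CHR", "SNP", "BP", "A1", "F_A", "F_U", "A2", "P", "OR")
  write.table(scan[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
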