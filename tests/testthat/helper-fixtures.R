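# Shared fixtures, built in code.

# tiny hand-made dataset: n samples x m variants with explicit genotypes
toy_dataset <- function(genotypes, phenotype = NULL, batch = NULL,
                        chrom = NULL, bp = NULL) {
  g <- as.matrix(genotypes)
  n <- nrow(g); m <- ncol(g)
  if (is.null(phenotype)) phenotype <- rep(c("case", "control"), length.out = n)
  if (is.null(batch)) batch <- rep("B1", n)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  genotype_dataset(
    g,
    variants = data.frame(chrom = chrom, rsid = sprintf("rs%03d", seq_len(m)),
                          bp = bp, a1 = rep("A", m), a2 = rep("G", m),
                          stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                         phenotype = phenotype, batch = batch,
                         sex = NA_character_, stringsAsFactors = FALSE))
}

# random dataset with missingness, for round-trip property tests
random_dataset <- function(n, m, miss = 0.05, seed = 1) {
  set.seed(seed)
  g <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)[rep(seq_len(m), each = n)]),
              n, m)
  g[matrix(runif(n * m) < miss, n, m)] <- NA
  toy_dataset(g, phenotype = sample(c("case", "control", NA), n, TRUE,
                                    prob = c(.45, .45, .1)))
}

# small cohort with one planted enriched set (shared across sba tests)
planted_cohort <- function(n = 400, n_blocks = 10, or = 1.8, n_causal = 5,
                           seed = 11, ...) {
  simulate_cohort(sim_config(
    n_cases = n / 2, n_controls = n / 2, n_blocks = n_blocks, n_sets = 10,
    causal_sets = list(list(set = "set01", n_causal = n_causal, or = or)),
    seed = seed, ...))
}

# independent HWE oracle: literal enumeration of the conditional
# distribution via the recurrence of genotype-table probabilities
# (different route from the package's direct log-factorial formula)
hwe_oracle <- function(h1, het, h2) {
  n <- h1 + het + h2
  na <- 2 * h1 + het
  rare <- min(na, 2 * n - na)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  # unnormalized probabilities by recurrence:
  # P(h+2)/P(h) = 4 * hom_r(h) * hom_c(h) / ((h+2)*(h+1))
  pr <- numeric(length(hs))
  pr[1] <- 1
  if (length(hs) > 1) for (i in 2:length(hs)) {
    h <- hs[i - 1]
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    pr[i] <- pr[i - 1] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
  }
  pr <- pr / sum(pr)
  obs <- pr[match(het, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# all 0/1 assignments of length n with k ones (exhaustive permutations)
all_assignments <- function(n, k) {
  combos <- combn(n, k)
  apply(combos, 2, function(ix) { y <- integer(n); y[ix] <- 1L; y })
}
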