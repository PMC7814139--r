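# Structured case-control cohort simulator.
#
# Population structure follows the Balding-Nichols model: each SNP has an
# ancestral frequency p0 ~ U(0.05, 0.5) and per-subpopulation frequencies
# p_k ~ Beta(p0(1-F)/F, (1-p0)(1-F)/F). Linkage disequilibrium is created
# at two levels: founder haplotypes carry ancestral LD (AR(1) Gaussian
# copula with exact Bernoulli(p) marginals, so r2 decays geometrically
# with SNP distance and vanishes across block boundaries), and each
# individual haplotype is a mosaic of the founders (geometric switch
# process emulating recombination). The founder pool is large enough that
# baseline pairwise kinship (about 2/n_founders in PI_HAT units) stays far
# below relatedness-pruning thresholds. Disease status is
# Bernoulli(logistic(alpha + sum beta_k g_k)) with alpha fixed by the
# baseline prevalence; case/control quotas are filled by rejection
# sampling (case-control ascertainment).

#' Simulation configuration
#'
#' @param n_cases,n_controls cohort quotas.
#' @param n_pops number of subpopulations.
#' @param fst Balding-Nichols divergence per subpopulation (scalar or
#'   vector of length `n_pops`), in (0, 1).
#' @param pop_props sampling proportions of the subpopulations (default
#'   equal).
#' @param n_blocks,block_size LD blocks and SNPs per block.
#' @param n_founders founder haplotypes per block and subpopulation
#'   (default 100; baseline PI_HAT between cohort members is about
#'   2/n_founders, so keep this well above 2/0.1875 when the relatedness
#'   stage is in play).
#' @param switch_prob per-SNP probability of switching founder within a
#'   block (recombination analogue).
#' @param founder_ar latent AR(1) coefficient of the founder-haplotype
#'   copula; adjacent-SNP founder LD, hence population r2, decays
#'   geometrically in this coefficient.
#' @param snp_spacing base pairs between adjacent SNPs in a block.
#' @param block_gap base pairs between blocks on the same chromosome.
#' @param genes_per_block genes tiling each block.
#' @param n_sets number of gene sets partitioning the gene universe.
#' @param causal_sets list of causal-set specs, each a list with elements
#'   `set` (name; defaults to successive sets), `n_causal` (SNPs),
#'   `or` (per-allele odds ratio, > 0) and optional `one_gene = TRUE` to
#'   concentrate all causal SNPs in a single gene.
#' @param baseline_prevalence disease probability of a zero-score
#'   individual, in (0, 1).
#' @param n_batches genotyping batch labels assigned round-robin.
#' @param seed RNG seed; all randomness flows from it.
#' @return a validated config list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 500, n_controls = 500, n_pops = 1,
                       fst = 0.02, pop_props = NULL, n_blocks = 40,
                       block_size = 50, n_founders = 200, switch_prob = 0.05,
                       founder_ar = 0.9, snp_spacing = 10000, block_gap = 1e6,
                       genes_per_block = 5, n_sets = 45, causal_sets = NULL,
                       baseline_prevalence = 0.2, n_batches = 2, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_cases >= 1, n_controls >= 1, n_pops >= 1, n_blocks >= 1,
            block_size >= 2, n_founders >= 2,
            baseline_prevalence > 0, baseline_prevalence < 1)
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie in (0,1)")
  cfg$fst <- rep_len(fst, n_pops)
  if (is.null(pop_props)) cfg$pop_props <- rep(1 / n_pops, n_pops)
  cfg$pop_props <- cfg$pop_props / sum(cfg$pop_props)
  if (!is.null(causal_sets)) {
    for (cs in causal_sets) {
      if (is.null(cs$n_causal) || is.null(cs$or))
        stop("each causal set needs n_causal and or")
      if (cs$or <= 0) stop("odds_ratio must be > 0")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

# founder-mosaic genotypes for a vector of population labels
.sim_genotypes <- function(pop, founders, block_cols, n_founders, switch_prob) {
  n <- length(pop)
  m <- sum(lengths(block_cols))
  G <- matrix(0L, n, m)
  for (k in sort(unique(pop))) {
    idx <- which(pop == k)
    H <- 2L * length(idx)
    Fk <- founders[[k]]
    for (cols in block_cols) {
      L <- length(cols)
      D <- matrix(sample.int(n_founders, H * L, replace = TRUE), H, L)
      W <- matrix(runif(H * L) < switch_prob, H, L)
      P <- matrix(1L, H, L)  # column of the most recent founder switch
      if (L > 1) for (l in 2:L) {
        P[, l] <- P[, l - 1L]
        P[W[, l], l] <- l
      }
      fid <- matrix(D[cbind(rep(seq_len(H), L), as.vector(P))], H, L)
      hap <- matrix(Fk[cbind(as.vector(fid), rep(cols, each = H))], H, L)
      G[idx, cols] <- hap[seq_along(idx), , drop = FALSE] +
        hap[length(idx) + seq_along(idx), , drop = FALSE]
    }
  }
  G
}

#' Simulate a structured case-control cohort with known truth
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (a [genotype_dataset()]), `genes`
#'   (gene coordinate data.frame), `sets` (a [gene_set_collection()]
#'   partitioning the genes) and `truth` (causal SNPs with log-odds
#'   effects, enriched set names, per-sample population labels, planted
#'   artifacts, seed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nb <- config$n_blocks; L <- config$block_size
  m <- nb * L

  # variant map: blocks laid out over autosomes 1..22
  chrom_of_block <- as.character(((seq_len(nb) - 1L) %% 22L) + 1L)
  bp <- integer(m); chrom <- character(m)
  block_cols <- vector("list", nb)
  within_idx <- ave(seq_len(nb), chrom_of_block, FUN = seq_along)
  for (b in seq_len(nb)) {
    cols <- (b - 1L) * L + seq_len(L)
    block_cols[[b]] <- cols
    chrom[cols] <- chrom_of_block[b]
    base <- (within_idx[b] - 1L) * (L * config$snp_spacing + config$block_gap)
    bp[cols] <- as.integer(base + seq_len(L) * config$snp_spacing)
  }
  variants <- data.frame(chrom = chrom, rsid = sprintf("rs%06d", seq_len(m)),
                         bp = bp, a1 = "A", a2 = "G",
                         stringsAsFactors = FALSE)

  # Balding-Nichols frequencies and founder haplotypes with ancestral LD
  p0 <- runif(m, 0.05, 0.5)
  nf <- config$n_founders; ar <- config$founder_ar
  founders <- vector("list", config$n_pops)
  for (k in seq_len(config$n_pops)) {
    Fk <- config$fst[k]
    pk <- rbeta(m, p0 * (1 - Fk) / Fk, (1 - p0) * (1 - Fk) / Fk)
    pk <- pmin(pmax(pk, 1e-4), 1 - 1e-4)
    Fmat <- matrix(0L, nf, m)
    for (cols in block_cols) {
      Lb <- length(cols)
      Z <- matrix(rnorm(nf * Lb), nf, Lb)
      if (Lb > 1) for (l in 2:Lb)
        Z[, l] <- ar * Z[, l - 1] + sqrt(1 - ar^2) * Z[, l]
      thr <- matrix(qnorm(pk[cols]), nf, Lb, byrow = TRUE)
      Fmat[, cols] <- (Z < thr) * 1L
    }
    founders[[k]] <- Fmat
  }

  # genes tile the blocks; sets partition the genes
  gpb <- config$genes_per_block
  n_genes <- nb * gpb
  gene_rows <- vector("list", n_genes)
  gid <- 0L
  snp_gene <- integer(m)
  for (b in seq_len(nb)) {
    chunks <- split(block_cols[[b]], cut(seq_len(L), gpb, labels = FALSE))
    for (ch in chunks) {
      gid <- gid + 1L
      gene_rows[[gid]] <- data.frame(
        gene_id = gid, chrom = chrom_of_block[b],
        start = min(bp[ch]), end = max(bp[ch]),
        symbol = sprintf("G%04d", gid), stringsAsFactors = FALSE)
      snp_gene[ch] <- gid
    }
  }
  genes <- do.call(rbind, gene_rows)
  perm <- sample.int(n_genes)
  set_of_gene <- integer(n_genes)
  set_of_gene[perm] <- rep_len(seq_len(config$n_sets), n_genes)
  set_names <- sprintf("set%02d", seq_len(config$n_sets))
  sets <- gene_set_collection(
    setNames(lapply(seq_len(config$n_sets),
                    function(s) genes$gene_id[set_of_gene == s]), set_names),
    setNames(rep("simulated", config$n_sets), set_names))

  # causal SNPs inside genes of the designated sets
  causal_idx <- integer(0); causal_beta <- numeric(0)
  causal_gene <- integer(0); causal_set <- character(0)
  if (!is.null(config$causal_sets)) {
    auto <- 1L
    for (cs in config$causal_sets) {
      sname <- if (is.null(cs$set)) set_names[auto] else cs$set
      auto <- auto + 1L
      if (!sname %in% set_names) stop("unknown causal set: ", sname)
      member_genes <- sets$sets[[sname]]
      if (isTRUE(cs$one_gene)) {
        sizes <- table(snp_gene)[as.character(member_genes)]
        gsel <- member_genes[which(sizes >= cs$n_causal)[1]]
        if (is.na(gsel)) stop("no single gene large enough for n_causal")
        # isolate the causal gene: move any same-LD-block set member out of
        # the set (swapped with an out-of-set gene from another block), so
        # that leave-one-gene-out re-tests are not confounded by LD proxies
        blk <- function(g) (g - 1L) %/% gpb + 1L
        mates <- setdiff(member_genes[blk(member_genes) == blk(gsel)], gsel)
        for (g0 in mates) {
          swap_cand <- setdiff(genes$gene_id[blk(genes$gene_id) != blk(gsel)],
                               unlist(sets$sets[sname]))
          g1 <- swap_cand[sample.int(length(swap_cand), 1)]
          s1 <- names(Filter(function(gg) g1 %in% gg, sets$sets))[1]
          sets$sets[[sname]] <- sort(c(setdiff(sets$sets[[sname]], g0), g1))
          if (!is.na(s1))
            sets$sets[[s1]] <- sort(c(setdiff(sets$sets[[s1]], g1), g0))
        }
        member_genes <- sets$sets[[sname]]
        cand <- which(snp_gene == gsel)
      } else {
        cand <- which(snp_gene %in% member_genes)
      }
      pick <- sample(cand, cs$n_causal)
      causal_idx <- c(causal_idx, pick)
      causal_beta <- c(causal_beta, rep(log(cs$or), length(pick)))
      causal_gene <- c(causal_gene, snp_gene[pick])
      causal_set <- c(causal_set, rep(sname, length(pick)))
    }
  }

  # rejection sampling to the case/control quotas
  alpha <- qlogis(config$baseline_prevalence)
  need_ca <- config$n_cases; need_co <- config$n_controls
  rows_g <- list(); rows_y <- integer(0); rows_pop <- integer(0)
  exp_p <- config$baseline_prevalence
  for (iter in seq_len(30)) {
    if (need_ca <= 0 && need_co <= 0) break
    batch_n <- min(50000L, max(200L, ceiling(1.3 * max(
      if (need_ca > 0) need_ca / exp_p else 0,
      if (need_co > 0) need_co / (1 - exp_p) else 0))))
    pop <- sample.int(config$n_pops, batch_n, replace = TRUE,
                      prob = config$pop_props)
    Gb <- .sim_genotypes(pop, founders, block_cols, config$n_founders,
                         config$switch_prob)
    score <- if (length(causal_idx))
      as.vector(Gb[, causal_idx, drop = FALSE] %*% causal_beta) else 0
    pcase <- plogis(alpha + score)
    y <- rbinom(batch_n, 1L, pcase)
    exp_p <- min(0.95, max(0.05, mean(y)))
    keep_ca <- which(y == 1L)[seq_len(min(need_ca, sum(y == 1L)))]
    keep_co <- which(y == 0L)[seq_len(min(need_co, sum(y == 0L)))]
    keep <- c(keep_ca, keep_co)
    rows_g[[length(rows_g) + 1L]] <- Gb[keep, , drop = FALSE]
    rows_y <- c(rows_y, y[keep])
    rows_pop <- c(rows_pop, pop[keep])
    need_ca <- need_ca - length(keep_ca)
    need_co <- need_co - length(keep_co)
  }
  if (need_ca > 0 || need_co > 0)
    stop("simulation error: could not reach requested case/control counts ",
         "within the iteration cap (prevalence too extreme?)")

  G <- do.call(rbind, rows_g)
  n <- nrow(G)
  ord <- sample.int(n)  # interleave cases and controls
  G <- G[ord, , drop = FALSE]
  y <- rows_y[ord]; popl <- rows_pop[ord]
  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    phenotype = ifelse(y == 1L, "case", "control"),
    batch = sprintf("B%d", ((seq_len(n) - 1L) %% config$n_batches) + 1L),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  ds <- genotype_dataset(G, variants, samples)

  truth <- list(
    causal = data.frame(rsid = variants$rsid[causal_idx],
                        beta = causal_beta, or = exp(causal_beta),
                        gene_id = causal_gene, set = causal_set,
                        stringsAsFactors = FALSE),
    enriched_sets = unique(causal_set),
    pop = popl,
    artifacts = data.frame(kind = character(), id = character(),
                           stringsAsFactors = FALSE),
    alpha = alpha, seed = config$seed)
  list(dataset = ds, genes = genes, sets = sets, truth = truth)
}

#' Implant QC pathologies into a dataset
#'
#' Adds or perturbs samples/markers so the QC cascade has known targets.
#' Supported kinds: `duplicate_sample` (copies a row with per-SNP flip
#' probability `epsilon`), `parent_child` (one allele transmitted from the
#' parent, one drawn from population frequencies), `batch_missingness`
#' (raises missingness by `delta` in one batch/phenotype stratum at
#' `n_snps` markers), `sample_missingness`, `marker_missingness` and
#' `hwe_violation` (replaces a marker with an excess-heterozygosity draw).
#'
#' @param ds a [genotype_dataset()].
#' @param artifact_spec list of specs, each a list with `kind` plus
#'   kind-specific fields (see Details in the source).
#' @param seed RNG seed.
#' @return list(`dataset`, `truth`) where `truth$artifacts` is a
#'   data.frame of (kind, id) pairs naming the planted targets.
#' @export
implant_artifacts <- function(ds, artifact_spec, seed = 1) {
  set.seed(seed)
  kinds <- c("duplicate_sample", "parent_child", "batch_missingness",
             "sample_missingness", "marker_missingness", "hwe_violation")
  art <- list()
  freq <- a1_freq(ds)
  for (sp in artifact_spec) {
    if (!sp$kind %in% kinds) stop("unknown artifact kind: ", sp$kind)
    if (sp$kind == "duplicate_sample") {
      src <- if (is.null(sp$sample)) sample(ds$samples$sample_id, 1) else sp$sample
      i <- match(src, ds$samples$sample_id)
      eps <- if (is.null(sp$epsilon)) 0.001 else sp$epsilon
      g <- ds$genotypes[i, ]
      if (eps > 0) {
        fl <- which(runif(length(g)) < eps & !is.na(g))
        for (j in fl) g[j] <- sample(setdiff(0:2, g[j]), 1)
      }
      new <- ds$samples[i, , drop = FALSE]
      new$sample_id <- paste0(src, "_dup")
      ds$genotypes <- rbind(ds$genotypes, g)
      ds$samples <- rbind(ds$samples, new)
      art[[length(art) + 1]] <- data.frame(kind = sp$kind,
                                           id = paste(src, new$sample_id, sep = "|"))
    } else if (sp$kind == "parent_child") {
      src <- if (is.null(sp$sample)) sample(ds$samples$sample_id, 1) else sp$sample
      i <- match(src, ds$samples$sample_id)
      g <- ds$genotypes[i, ]
      trans <- ifelse(is.na(g), NA_integer_,
                      ifelse(g == 2L, 1L, ifelse(g == 0L, 0L,
                             rbinom(length(g), 1L, 0.5))))
      other <- rbinom(length(g), 1L, pmin(pmax(freq, 0), 1))
      child <- trans + other
      new <- ds$samples[i, , drop = FALSE]
      new$sample_id <- paste0(src, "_child")
      new$phenotype <- "control"
      ds$genotypes <- rbind(ds$genotypes, as.integer(child))
      ds$samples <- rbind(ds$samples, new)
      art[[length(art) + 1]] <- data.frame(kind = sp$kind,
                                           id = paste(src, new$sample_id, sep = "|"))
    } else if (sp$kind == "batch_missingness") {
      batch <- if (is.null(sp$batch)) ds$samples$batch[1] else sp$batch
      pheno <- if (is.null(sp$phenotype)) "case" else sp$phenotype
      delta <- if (is.null(sp$delta)) 0.05 else sp$delta
      snps <- .pick_snps(ds, sp)
      rows <- which(ds$samples$batch == batch & ds$samples$phenotype == pheno)
      for (j in snps) {
        hit <- rows[runif(length(rows)) < delta]
        ds$genotypes[hit, j] <- NA_integer_
      }
      art[[length(art) + 1]] <- data.frame(kind = sp$kind,
                                           id = ds$variants$rsid[snps])
    } else if (sp$kind == "sample_missingness") {
      src <- if (is.null(sp$sample)) sample(ds$samples$sample_id, 1) else sp$sample
      i <- match(src, ds$samples$sample_id)
      rate <- if (is.null(sp$rate)) 0.05 else sp$rate
      hit <- which(runif(n_variants(ds)) < rate)
      ds$genotypes[i, hit] <- NA_integer_
      art[[length(art) + 1]] <- data.frame(kind = sp$kind, id = src)
    } else if (sp$kind == "marker_missingness") {
      snps <- .pick_snps(ds, sp)
      rate <- if (is.null(sp$rate)) 0.05 else sp$rate
      for (j in snps) {
        hit <- which(runif(n_samples(ds)) < rate)
        ds$genotypes[hit, j] <- NA_integer_
      }
      art[[length(art) + 1]] <- data.frame(kind = sp$kind,
                                           id = ds$variants$rsid[snps])
    } else if (sp$kind == "hwe_violation") {
      snps <- .pick_snps(ds, sp, default_n = 10)
      for (j in snps) {
        ds$genotypes[, j] <- sample(c(0L, 1L, 2L), n_samples(ds),
                                    replace = TRUE, prob = c(0.05, 0.9, 0.05))
      }
      art[[length(art) + 1]] <- data.frame(kind = sp$kind,
                                           id = ds$variants$rsid[snps])
    }
  }
  truth <- list(artifacts = if (length(art)) do.call(rbind, art) else
    data.frame(kind = character(), id = character()))
  ds$samples <- ds$samples[, c("sample_id", "phenotype", "batch", "sex")]
  rownames(ds$samples) <- NULL
  rownames(ds$genotypes) <- NULL
  validate_dataset(ds)
  list(dataset = ds, truth = truth)
}

.pick_snps <- function(ds, sp, default_n = 100) {
  if (!is.null(sp$snps)) {
    if (is.character(sp$snps)) match(sp$snps, ds$variants$rsid) else sp$snps
  } else {
    n <- if (is.null(sp$n_snps)) default_n else sp$n_snps
    sample(n_variants(ds), n)
  }
}

#' Random null gene-set landscape
#'
#' Draws `n_sets` gene sets of random sizes over a gene universe, for
#' type-I-error studies (disjointness not required).
#'
#' @param n_sets number of sets (>= 1).
#' @param size_range integer vector `c(min, max)` of set sizes.
#' @param genes gene coordinate data.frame (the universe).
#' @param seed RNG seed.
#' @return a [gene_set_collection()].
#' @export
make_null_set_landscape <- function(n_sets, size_range, genes, seed = 1) {
  stopifnot(n_sets >= 1, length(size_range) == 2)
  if (size_range[2] > nrow(genes))
    stop("size_range exceeds the gene universe (", nrow(genes), " genes)")
  set.seed(seed)
  rng <- size_range[1]:size_range[2]
  sizes <- rng[sample.int(length(rng), n_sets, replace = TRUE)]
  nm <- sprintf("null_set%02d", seq_len(n_sets))
  gene_set_collection(
    setNames(lapply(sizes, function(s) sort(sample(genes$gene_id, s))), nm),
    setNames(rep("null landscape", n_sets), nm))
}
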