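# Shared fixtures and independent oracles, built in code.

# Tiny hand-specified dataset: `geno` is n_snps x n_ind.
toy_dataset <- function(geno, phenotype, chromosome = "1",
                        positions = NULL, ids = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(positions)) positions <- 1000L * seq_len(n)
  if (is.null(ids)) ids <- paste0("rs", seq_len(n))
  genotype_dataset(
    data.frame(snp_id = ids, chromosome = chromosome, position_bp = positions,
               stringsAsFactors = FALSE),
    geno, phenotype)
}

# Dataset of n independent Binomial(2, f) SNPs with random phenotype.
random_dataset <- function(n_snps, n_ind, seed, maf_range = c(0.1, 0.5),
                           n_case = floor(n_ind / 2)) {
  set.seed(seed)
  f <- runif(n_snps, maf_range[1], maf_range[2])
  g <- matrix(rbinom(n_snps * n_ind, 2L, rep(f, n_ind)), n_snps, n_ind)
  toy_dataset(g, rep(c("case", "control"), c(n_case, n_ind - n_case)))
}

# Brute-force mutual information in bits: explicit double loop over
# cells, independent of the package implementation.
oracle_mi <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      p <- tab[i, j] / n
      if (p > 0) mi <- mi + p * log(p / (px[i] * py[j]), base = 2)
    }
  }
  mi
}

# Independent entropy oracle (bits).
oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = 2))
}

# Independent information-gain oracle: H(class) - weighted child
# entropies, written directly from the definition.
oracle_gain <- function(parent, left, right) {
  n <- sum(parent)
  g <- oracle_entropy(parent)
  if (sum(left) > 0) g <- g - sum(left) / n * oracle_entropy(left)
  if (sum(right) > 0) g <- g - sum(right) / n * oracle_entropy(right)
  g
}

# Exhaustive pairwise AUC: fraction of (case, control) pairs where the
# case scores higher, ties counted half.
oracle_auc <- function(scores, labels) {
  cases <- scores[as.logical(labels)]
  ctrls <- scores[!as.logical(labels)]
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}

# Exact HWE enumeration oracle: conditional probability of every
# feasible heterozygote count given the allele counts, via log
# factorials assembled from the textbook formula.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa   # rare-or-not does not matter: symmetric
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logp <- sapply(hets, function(h) {
    haa <- (n_a - h) / 2
    hAA <- n - h - haa
    lfactorial(n) - lfactorial(h) - lfactorial(haa) - lfactorial(hAA) +
      h * log(2) - (lfactorial(2 * n) - lfactorial(n_a) -
                      lfactorial(2 * n - n_a))
  })
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[hets == n_Aa]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Coarse exhaustive grid search over the 5 free parameters of a
# 2-child binary latent class model with 2 latent states; returns the
# best log-likelihood on the grid for the given 2x2 cell counts.
oracle_lcm_grid <- function(counts, step = 0.05) {
  grid <- seq(step / 2, 1 - step / 2, by = step)
  g4 <- expand.grid(a0 = grid, a1 = grid, b0 = grid, b1 = grid)
  best <- -Inf
  for (p1 in grid) {
    p00 <- p1 * (1 - g4$a1) * (1 - g4$b1) + (1 - p1) * (1 - g4$a0) * (1 - g4$b0)
    p01 <- p1 * (1 - g4$a1) * g4$b1 + (1 - p1) * (1 - g4$a0) * g4$b0
    p10 <- p1 * g4$a1 * (1 - g4$b1) + (1 - p1) * g4$a0 * (1 - g4$b0)
    p11 <- p1 * g4$a1 * g4$b1 + (1 - p1) * g4$a0 * g4$b0
    ll <- counts[1, 1] * log(p00) + counts[1, 2] * log(p01) +
      counts[2, 1] * log(p10) + counts[2, 2] * log(p11)
    best <- max(best, max(ll))
  }
  best
}

# Density-reachability closure oracle for DBSCAN on a full distance
# matrix: core points, transitive closure over core-core edges, border
# attachment to the smallest-index core neighbor, noise as singletons.
oracle_dbscan <- function(D, R, N_min) {
  n <- nrow(D)
  nbr <- lapply(seq_len(n), function(i) setdiff(which(D[i, ] <= R), i))
  core <- vapply(nbr, length, 1L) >= N_min
  lab <- integer(n)
  nl <- 0L
  repeat {
    seed_pt <- which(core & lab == 0L)
    if (!length(seed_pt)) break
    nl <- nl + 1L
    comp <- seed_pt[1L]
    repeat {
      grow <- unique(unlist(nbr[comp]))
      grow <- grow[core[grow] & !(grow %in% comp)]
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    lab[comp] <- nl
  }
  for (i in which(core)) {
    for (w in nbr[[i]]) if (!core[w] && lab[w] == 0L) lab[w] <- lab[i]
  }
  for (i in which(lab == 0L)) { nl <- nl + 1L; lab[i] <- nl }
  out <- split(seq_len(n), lab)
  names(out) <- NULL
  out[order(vapply(out, min, 1L))]
}

# Canonical form of a partition for comparison.
canon_partition <- function(cl) {
  cl <- lapply(cl, function(x) sort(as.integer(x)))
  cl[order(vapply(cl, min, 1L))]
}
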