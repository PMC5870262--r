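# Haplotype-block case-control genotype simulator with planted causal
# SNPs.  Blocks of limited haplotype diversity reproduce the local-LD
# property the multilocus methods exploit; disease status follows
# genotype-dependent penetrances derived from a genetic model, a
# genotype relative risk and a population prevalence.

#' Simulation configuration
#'
#' Defaults follow the reference study design: 20,000 SNPs, 2,000 cases
#' and 2,000 controls, 10 causal SNPs, prevalence 0.01, genetic model
#' among additive/dominant/recessive with GRR in {1.2, 1.5, 1.8} and
#' causal MAF drawn in one of [0.05,0.15] / [0.15,0.25] / [0.25,0.35].
#'
#' @param n_snps,n_cases,n_controls Panel and sample sizes.
#' @param n_causal Number of planted causal SNPs.
#' @param genetic_model `"additive"`, `"dominant"` or `"recessive"`.
#' @param grr Genotype relative risk (>= 1).
#' @param causal_maf_interval Closed interval of admissible causal-SNP
#'   population MAF.
#' @param prevalence Population disease prevalence.
#' @param block_size_range Haplotype-block lengths (SNPs), drawn
#'   uniformly.
#' @param haplotypes_per_block Distinct haplotypes per block.
#' @param recomb_between_blocks Probability of an independent haplotype
#'   re-draw at each block boundary (1 = independent blocks).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 20000, n_cases = 2000, n_controls = 2000,
                       n_causal = 10,
                       genetic_model = c("additive", "dominant", "recessive"),
                       grr = 1.5, causal_maf_interval = c(0.25, 0.35),
                       prevalence = 0.01, block_size_range = c(5, 15),
                       haplotypes_per_block = 5,
                       recomb_between_blocks = 0.5) {
  genetic_model <- match.arg(genetic_model)
  stopifnot(n_causal <= n_snps, prevalence > 0, prevalence < 1, grr >= 1,
            causal_maf_interval[1] > 0, causal_maf_interval[2] <= 0.5,
            haplotypes_per_block >= 2, recomb_between_blocks >= 0,
            recomb_between_blocks <= 1)
  if (haplotypes_per_block > 2^block_size_range[1])
    stop("haplotypes_per_block exceeds the diversity of the shortest block")
  structure(as.list(environment()), class = "sim_config")
}

#' Genotype penetrances from a genetic model
#'
#' Relative risks per risk-allele count are `(grr, 2*grr - 1)` for the
#' additive model, `(grr, grr)` for dominant and `(1, grr)` for
#' recessive.  The baseline penetrance solves
#' `K = f0 * (p0 + g1*p1 + g2*p2)` under Hardy-Weinberg genotype
#' frequencies at risk-allele frequency `q`.
#'
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @param grr Genotype relative risk (>= 1).
#' @param q Risk allele frequency in `(0, 1)`.
#' @param prevalence Population prevalence `K` in `(0, 1)`.
#' @return Numeric `c(f0, f1, f2)`: penetrance per risk-allele count.
#' @export
penetrances <- function(model = c("additive", "dominant", "recessive"),
                        grr, q, prevalence) {
  model <- match.arg(model)
  stopifnot(q > 0, q < 1, prevalence > 0, prevalence < 1, grr >= 1)
  g <- switch(model,
              additive = c(grr, 2 * grr - 1),
              dominant = c(grr, grr),
              recessive = c(1, grr))
  p <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  f0 <- prevalence / sum(p * c(1, g))
  f <- f0 * c(1, g)
  if (any(f > 1)) stop("infeasible configuration: penetrance exceeds 1")
  f
}

#' Build a haplotype-block population sampler
#'
#' Partitions the panel into blocks of lengths drawn from
#' `block_size_range`; each block carries `haplotypes_per_block` distinct
#' 0/1 haplotypes with Dirichlet(1) frequencies.  A gamete is a chain of
#' per-block haplotype draws: at each block boundary the draw is
#' redrawn from the block's frequencies with probability
#' `recomb_between_blocks`, otherwise the previous index is carried
#' over (creating between-block LD).  A genotype is the allele sum of
#' two independent gametes.  SNP positions are laid out at 1 kb spacing
#' on one chromosome.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return A list of class `sim_population` with per-block haplotypes,
#'   frequencies and column indices, per-SNP allele-1 frequency `freq1`
#'   and `maf`, and `positions`.
#' @export
simulate_population <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_snps
  H <- config$haplotypes_per_block
  lens <- integer(0)
  while (sum(lens) < n) {
    lens <- c(lens, sample(config$block_size_range[1]:config$block_size_range[2], 1L))
  }
  lens[length(lens)] <- lens[length(lens)] - (sum(lens) - n)
  if (lens[length(lens)] == 0L) lens <- lens[-length(lens)]
  blocks <- vector("list", length(lens))
  start <- 1L
  for (b in seq_along(lens)) {
    len <- lens[b]
    Hb <- min(H, 2^len)  # short trailing blocks carry what diversity they can
    # distinct haplotypes: site frequencies then Bernoulli draws;
    # duplicated draws are replaced by unused patterns
    site_f <- runif(len, 0.1, 0.9)
    haps <- matrix(rbinom(Hb * len, 1L, rep(site_f, each = Hb)), Hb, len)
    for (tries in 1:50) {
      dup <- duplicated(haps)
      if (!any(dup)) break
      haps[dup, ] <- rbinom(sum(dup) * len, 1L, rep(site_f, each = sum(dup)))
    }
    if (anyDuplicated(haps)) {
      all_pat <- as.matrix(expand.grid(rep(list(0:1), len)))
      used <- apply(haps[!duplicated(haps), , drop = FALSE], 1L, paste, collapse = "")
      free <- all_pat[!(apply(all_pat, 1L, paste, collapse = "") %in% used), ,
                      drop = FALSE]
      need <- sum(duplicated(haps))
      haps[duplicated(haps), ] <- free[sample.int(nrow(free), need), ]
    }
    freq <- rgamma_dirichlet(Hb)
    blocks[[b]] <- list(haps = haps, freq = freq,
                        cols = start:(start + len - 1L))
    start <- start + len
  }
  freq1 <- numeric(n)
  for (b in blocks)
    freq1[b$cols] <- as.vector(b$freq %*% b$haps)
  structure(list(blocks = blocks, n_snps = n,
                 freq1 = freq1, maf = pmin(freq1, 1 - freq1),
                 positions = 1000L * seq_len(n),
                 recomb = config$recomb_between_blocks),
            class = "sim_population")
}

rgamma_dirichlet <- function(m) {
  e <- -log(runif(m))
  e / sum(e)
}

# m gametes as an m x n_blocks matrix of haplotype indices.  A latent
# uniform is carried along the gamete and redrawn with probability
# `recomb` at each block boundary; each block maps it through the
# inverse CDF of its own haplotype frequencies, so every block's
# marginal haplotype distribution is exact while consecutive blocks
# stay correlated (between-block LD).
draw_gametes <- function(pop, m) {
  nb <- length(pop$blocks)
  idx <- matrix(0L, m, nb)
  u <- runif(m)
  for (b in seq_len(nb)) {
    if (b > 1L) {
      sw <- runif(m) < pop$recomb
      ns <- sum(sw)
      if (ns > 0L) u[sw] <- runif(ns)
    }
    idx[, b] <- findInterval(u, cumsum(pop$blocks[[b]]$freq)) + 1L
  }
  idx
}

# Genotypes (m x n_snps) from two gamete index matrices.
materialize_genotypes <- function(pop, idxA, idxB) {
  m <- nrow(idxA)
  G <- matrix(0L, m, pop$n_snps)
  for (b in seq_along(pop$blocks)) {
    bl <- pop$blocks[[b]]
    G[, bl$cols] <- bl$haps[idxA[, b], , drop = FALSE] +
      bl$haps[idxB[, b], , drop = FALSE]
  }
  G
}

# Genotype at single SNPs from gamete indices (m x n_causal).
causal_genotypes <- function(pop, idxA, idxB, snp_idx) {
  vapply(snp_idx, function(s) {
    b <- which(vapply(pop$blocks, function(bl) s %in% bl$cols, TRUE))[1L]
    off <- match(s, pop$blocks[[b]]$cols)
    pop$blocks[[b]]$haps[idxA[, b], off] + pop$blocks[[b]]$haps[idxB[, b], off]
  }, integer(nrow(idxA)))
}

# Disease probability per individual given causal risk-allele dosages
# (m x n_causal) and per-causal penetrance triplets (3 x n_causal), each
# computed at the population prevalence K.  Loci combine on the
# multiplicative relative-risk scale, P(aff | g) = K * prod_i
# f_i(g_i) / K, so every causal SNP keeps its configured marginal GRR
# and the unconditioned prevalence stays K (the penetrance triplets
# already absorb the per-locus normalization E[rr_i]).
disease_prob <- function(dosage, pen, prevalence) {
  m <- nrow(dosage)
  p <- rep(prevalence, m)
  for (j in seq_len(ncol(dosage)))
    p <- p * pen[dosage[, j] + 1L, j] / prevalence
  pmin(p, 1)
}

# Shared setup: population draw (re-drawn until enough SNPs fall in the
# causal MAF interval), causal-SNP choice, per-SNP penetrances.
sim_setup <- function(config, seed) {
  lo <- config$causal_maf_interval[1]; hi <- config$causal_maf_interval[2]
  pop <- NULL
  for (attempt in 1:20) {
    pop <- simulate_population(config, seed = seed + 1000L * (attempt - 1L))
    eligible <- which(pop$maf >= lo & pop$maf <= hi)
    if (length(eligible) >= config$n_causal) break
    pop <- NULL
  }
  if (is.null(pop))
    stop("infeasible causal MAF interval: too few eligible SNPs after 20 draws")
  set.seed(seed + 500000L)
  causal <- sort(sample(eligible, config$n_causal))
  pen <- vapply(causal, function(s)
    penetrances(config$genetic_model, config$grr, pop$maf[s],
                config$prevalence),
    numeric(3))
  pen <- matrix(pen, nrow = 3)
  list(pop = pop, causal = causal, pen = pen,
       minor_is_1 = pop$freq1[causal] <= 0.5,
       prevalence = config$prevalence)
}

#' Simulate an unconditioned population cohort
#'
#' Draws `n` individuals from the block-haplotype population without
#' case/control ascertainment and returns their disease status and
#' risk-allele dosages at the planted causal SNPs.  Genotypes are not
#' materialized, so large cohorts are cheap; used to calibrate
#' prevalence and effect-size recovery.
#'
#' @param config A [sim_config()].
#' @param n Number of individuals.
#' @param seed RNG seed (shares the population/causal-SNP choice with
#'   [simulate_case_control()] at the same seed).
#' @return A list with `status` (logical, TRUE = affected), `dosage`
#'   (n x n_causal risk-allele counts), `causal_index`, `penetrances`,
#'   `population`.
#' @export
simulate_cohort <- function(config, n, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  su <- sim_setup(config, seed)
  idxA <- draw_gametes(su$pop, n)
  idxB <- draw_gametes(su$pop, n)
  g <- causal_genotypes(su$pop, idxA, idxB, su$causal)
  dos <- g
  for (j in seq_along(su$causal))
    if (!su$minor_is_1[j]) dos[, j] <- 2L - g[, j]
  p_aff <- disease_prob(dos, su$pen, config$prevalence)
  status <- runif(n) < p_aff
  list(status = status, dosage = dos, causal_index = su$causal,
       penetrances = su$pen, population = su$pop)
}

#' Simulate a case-control dataset with planted causal SNPs
#'
#' Builds a block-haplotype population, plants `n_causal` causal SNPs
#' with population MAF inside `causal_maf_interval` (the risk allele is
#' the minor allele), assigns disease status from per-SNP penetrances
#' combined multiplicatively on the relative-risk scale — so every
#' causal SNP keeps its configured marginal GRR and the unconditioned
#' prevalence stays at `K` — and rejection-samples until exactly
#' `n_cases` cases and `n_controls` controls are collected.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (the whole draw is deterministic given it).
#' @return A list of class `sim_dataset`: `dataset` (a
#'   [genotype_dataset()]), `causal_snp_ids`, `causal_index`,
#'   `penetrances` (3 x n_causal), `population`.
#' @export
simulate_case_control <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  su <- sim_setup(config, seed)
  pop <- su$pop; causal <- su$causal; pen <- su$pen
  minor_is_1 <- su$minor_is_1

  n_case_left <- config$n_cases
  n_ctrl_left <- config$n_controls
  keepA <- list(); keepB <- list(); status <- list()
  batch <- max(2000L, ceiling((config$n_cases + config$n_controls) / 10))
  for (rounds in 1:5000) {
    if (n_case_left <= 0L && n_ctrl_left <= 0L) break
    idxA <- draw_gametes(pop, batch)
    idxB <- draw_gametes(pop, batch)
    g <- causal_genotypes(pop, idxA, idxB, causal)
    dos <- g
    for (j in seq_along(causal))
      if (!minor_is_1[j]) dos[, j] <- 2L - g[, j]
    p_aff <- disease_prob(dos, pen, config$prevalence)
    aff <- runif(batch) < p_aff
    take_case <- which(aff)[seq_len(min(sum(aff), n_case_left))]
    take_ctrl <- which(!aff)[seq_len(min(sum(!aff), n_ctrl_left))]
    take <- c(take_case, take_ctrl)
    if (length(take)) {
      keepA[[length(keepA) + 1L]] <- idxA[take, , drop = FALSE]
      keepB[[length(keepB) + 1L]] <- idxB[take, , drop = FALSE]
      status[[length(status) + 1L]] <-
        rep(c("case", "control"), c(length(take_case), length(take_ctrl)))
      n_case_left <- n_case_left - length(take_case)
      n_ctrl_left <- n_ctrl_left - length(take_ctrl)
    }
  }
  if (n_case_left > 0L || n_ctrl_left > 0L)
    stop("rejection sampling failed to reach the configured case/control counts")
  idxA <- do.call(rbind, keepA); idxB <- do.call(rbind, keepB)
  status <- unlist(status)
  ord <- order(status == "control")  # cases first, stable
  G <- materialize_genotypes(pop, idxA[ord, , drop = FALSE],
                             idxB[ord, , drop = FALSE])
  ids <- sprintf("snp%05d", seq_len(pop$n_snps))
  ds <- genotype_dataset(
    data.frame(snp_id = ids, chromosome = "1",
               position_bp = pop$positions, stringsAsFactors = FALSE),
    t(G), status[ord])
  structure(list(dataset = ds, causal_snp_ids = ids[causal],
                 causal_index = causal, penetrances = pen,
                 population = pop),
            class = "sim_dataset")
}
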